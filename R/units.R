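#' @title Unit handling for intakes, concentrations and reference values
#'
#' @description
#' All quantities in the package carry an explicit unit string. Units are a
#' small closed dialect: a mass prefix (`g`, `mg`, `ug`; `µg` is accepted
#' as a synonym of `ug`), optionally per kilogram of dry extract (`/kg`),
#' optionally per kilogram of body weight (`/kg bw`), and optionally per time
#' (`/day`, `/week`) or per consumption event (no time part together with
#' `/kg bw`). Conversions are powers of 10^3 on the mass part and a factor 7
#' between daily and weekly bases; any other conversion is a dimension error.
#'
#' @name units
NULL

.mass_factors <- c(g = 1, mg = 1e-3, ug = 1e-6)

# Parse a unit string into mass factor + dimension signature.
# Signature: per_kg (extract), per_bw, time in {none, day, week, event}.
parse_unit <- function(u) {
  stopifnot(is.character(u), length(u) == 1L)
  raw <- u
  u <- gsub("µ", "u", trimws(u))
  u <- gsub("\\s*/\\s*", "/", u)
  parts <- strsplit(u, "/", fixed = TRUE)[[1]]
  mass <- parts[1]
  if (!mass %in% names(.mass_factors)) {
    stop("unrecognised mass unit '", mass, "' in '", raw, "'", call. = FALSE)
  }
  per_kg <- FALSE
  per_bw <- FALSE
  time <- "none"
  for (p in parts[-1]) {
    if (p == "kg") {
      per_kg <- TRUE
    } else if (p %in% c("kg bw", "kgbw", "kg_bw")) {
      per_bw <- TRUE
    } else if (p %in% c("day", "d")) {
      time <- "day"
    } else if (p %in% c("week", "wk")) {
      time <- "week"
    } else if (p == "event") {
      time <- "event"
    } else {
      stop("unrecognised unit component '", p, "' in '", raw, "'", call. = FALSE)
    }
  }
  list(
    mass_factor = unname(.mass_factors[mass]),
    per_kg = per_kg, per_bw = per_bw, time = time
  )
}

.time_days <- c(day = 1, week = 7)

#' Convert a value between compatible units
#'
#' Mass prefixes convert by powers of 1000; `day` and `week` bases convert by
#' a factor 7 (a per-day rate times 7 is the per-week rate, so the numeric
#' value grows when moving day -> week). Quantities per kg of extract, per kg
#' of body weight, per event and plain masses are mutually incompatible.
#'
#' @param value numeric vector.
#' @param from,to unit strings, e.g. `"ug/kg bw/day"`, `"mg/kg bw/week"`.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_units(58.2, "ug/kg bw/day", "ug/kg bw/week") # 407.4
#' convert_units(0.0003, "mg/kg bw/day", "ug/kg bw/day") # 0.3
#' @export
convert_units <- function(value, from, to) {
  f <- parse_unit(from)
  t <- parse_unit(to)
  if (f$per_kg != t$per_kg || f$per_bw != t$per_bw) {
    stop("incompatible dimensions: '", from, "' vs '", to, "'", call. = FALSE)
  }
  same_time <- f$time == t$time
  both_rates <- f$time %in% c("day", "week") && t$time %in% c("day", "week")
  if (!same_time && !both_rates) {
    stop("incompatible time basis: '", from, "' vs '", to, "'", call. = FALSE)
  }
  out <- value * f$mass_factor / t$mass_factor
  if (!same_time) {
    # value per day -> per week multiplies by 7
    out <- out * .time_days[[t$time]] / .time_days[[f$time]]
  }
  out
}

#' @rdname convert_units
#' @param a,b unit strings.
#' @return `units_compatible`: logical.
#' @export
units_compatible <- function(a, b) {
  ok <- TRUE
  tryCatch(convert_units(1, a, b), error = function(e) ok <<- FALSE)
  ok
}

# Deterministic sub-seed derivation: every stochastic stage derives its own
# seed from the root seed plus a string key, so streams are independent and
# the whole pipeline is reproducible from one integer.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(key)
  h <- sum(chars * seq_along(chars)) %% 65521
  as.integer((abs(seed) %% 1e6) * 2027 + h * 31 + 1)
}
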