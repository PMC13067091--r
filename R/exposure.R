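#' @title Monte Carlo exposure engine
#'
#' @description
#' Seeded Monte Carlo simulation of element intake under four scenarios:
#' the baseline reference diet, chronic consumption of botanical extracts
#' alone, the two combined, and acute (per-event) botanical consumption for
#' Ni. Essential-element intake from botanicals is concentration (mg/kg)
#' times total consumption (g/day) / 1000, in mg/day; toxic-element intake is
#' concentration (ug/kg) times body-weight-normalized consumption
#' (g/kg bw/day) / 1000, in ug/kg bw/day. Concentration and consumption are
#' sampled independently, one fresh draw of each per iteration.
#'
#' @name exposure
NULL

.scenarios <- c("baseline", "botanicals", "combined", "acute_botanicals")

new_exposure_draws <- function(element, scenario, basis, units, values,
                               seed, streams = NULL) {
  stopifnot(scenario %in% .scenarios, all(values > 0))
  structure(
    list(element = element, scenario = scenario, basis = basis, units = units,
         values = as.numeric(values), seed = seed, n_iter = length(values),
         streams = streams),
    class = "exposure_draws"
  )
}

#' @export
print.exposure_draws <- function(x, ...) {
  s <- summarize_draws(x)
  cat("<exposure_draws> ", x$element, " / ", x$scenario, " (", x$units,
      ", n_iter = ", x$n_iter, ")\n", sep = "")
  cat(sprintf("  mean %.4g  sd %.4g  median %.4g  P5-P95 %.4g-%.4g\n",
              s$mean, s$sd, s$median, s$p5, s$p95))
  invisible(x)
}

#' Simulate chronic intake from botanical extracts alone
#'
#' Per iteration, one concentration draw from the element's fitted
#' distribution is multiplied by one consumption draw (lognormal from the
#' published moments) and divided by 1000. Essentials use the total
#' consumption pattern (g/day, result in mg/day); toxic elements use the
#' body-weight-normalized pattern (g/kg bw/day, result in ug/kg bw/day; an
#' Al concentration in mg/kg is first expressed in ug/kg).
#'
#' @param registry an `rba_registry`.
#' @param element element symbol.
#' @param n_iter Monte Carlo iterations (published design: 100 000).
#' @param seed root seed; concentration and consumption sub-streams are
#'   derived from it.
#' @return an `exposure_draws` (scenario `"botanicals"`); the raw
#'   concentration and consumption streams are kept in `$streams` for
#'   sensitivity analysis.
#' @export
simulate_botanicals_edi <- function(registry, element, n_iter = 1e5, seed = 1) {
  el <- get_element(registry, element)
  conc_spec <- get_concentration_dist(registry, element)
  mode <- if (el$class == "essential") "chronic_total_g_per_day" else "chronic_g_per_kgbw_day"
  cons <- get_consumption(registry, mode)
  cons_spec <- lognormal_from_moments(cons$mean, cons$sd)

  conc <- dist_sample(conc_spec, n_iter, derive_seed(seed, paste0(element, "-botanicals-conc")))
  rate <- dist_sample(cons_spec, n_iter, derive_seed(seed, paste0(element, "-botanicals-cons")))

  # express the concentration in the mass prefix of the intake unit so that
  # conc x g-consumption / 1000 lands in canonical intake units
  target_conc_units <- if (el$class == "essential") "mg/kg" else "ug/kg"
  conc_canon <- convert_units(conc, el$concentration_units, target_conc_units)
  values <- conc_canon * rate / 1000
  new_exposure_draws(element, "botanicals", "daily", el$intake_units, values,
                     seed, streams = list(concentration = conc, consumption = rate))
}

#' Simulate baseline dietary intake
#'
#' Baseline intake is lognormal, moment-matched to the published adult
#' mean +/- SD for the element, in canonical intake units.
#'
#' @inheritParams simulate_botanicals_edi
#' @return an `exposure_draws` (scenario `"baseline"`).
#' @export
simulate_baseline <- function(registry, element, n_iter = 1e5, seed = 1) {
  el <- get_element(registry, element)
  b <- get_baseline_moments(registry, element)
  spec <- lognormal_from_moments(b$mean, b$sd)
  values <- dist_sample(spec, n_iter, derive_seed(seed, paste0(element, "-baseline")))
  new_exposure_draws(element, "baseline", "daily", el$intake_units, values, seed)
}

#' Combine baseline and botanicals exposure iteration-wise
#'
#' The combined scenario is the iteration-wise sum of the two independent
#' streams. The per-iteration botanical share of total intake is retained in
#' `$streams$botanical_share` (its mean is the "average contribution of
#' botanicals" summary).
#'
#' @param baseline,botanicals `exposure_draws` for the same element, basis
#'   and iteration count.
#' @return an `exposure_draws` (scenario `"combined"`).
#' @export
combine_exposure <- function(baseline, botanicals) {
  stopifnot(inherits(baseline, "exposure_draws"), inherits(botanicals, "exposure_draws"))
  if (baseline$element != botanicals$element) stop("element mismatch", call. = FALSE)
  if (baseline$basis != botanicals$basis) stop("basis mismatch", call. = FALSE)
  if (baseline$units != botanicals$units) stop("unit mismatch", call. = FALSE)
  if (baseline$n_iter != botanicals$n_iter) stop("n_iter mismatch", call. = FALSE)
  total <- baseline$values + botanicals$values
  new_exposure_draws(
    baseline$element, "combined", baseline$basis, baseline$units, total,
    botanicals$seed,
    streams = c(botanicals$streams,
                list(botanical_share = botanicals$values / total))
  )
}

#' Convert daily draws to a weekly basis
#'
#' Multiplies every iteration by 7 and, for body-weight-normalized ug
#' intakes, re-expresses the result in mg/kg bw/week — the basis of the Al
#' tolerable weekly intake.
#'
#' @param daily an `exposure_draws` with `basis == "daily"`.
#' @return an `exposure_draws` with `basis == "weekly"`.
#' @export
weekly_from_daily <- function(daily) {
  stopifnot(inherits(daily, "exposure_draws"))
  if (daily$basis != "daily") stop("draws are not on a daily basis", call. = FALSE)
  from <- daily$units
  to <- sub("/day$", "/week", from)
  if (grepl("^ug/kg bw", from)) to <- sub("^ug", "mg", to)
  values <- convert_units(daily$values, from, to)
  out <- new_exposure_draws(daily$element, daily$scenario, "weekly", to, values,
                            daily$seed, streams = daily$streams)
  out
}

#' Simulate acute (per-event) exposure from botanicals
#'
#' Only Ni has an acute assessment: one concentration draw times one acute
#' consumption draw (g/kg bw per event) / 1000, in ug/kg bw per event.
#'
#' @inheritParams simulate_botanicals_edi
#' @return an `exposure_draws` (scenario `"acute_botanicals"`, basis
#'   `"per-event"`).
#' @export
simulate_acute <- function(registry, element = "Ni", n_iter = 1e5, seed = 1) {
  el <- get_element(registry, element)
  if (el$class != "toxic") stop("acute assessment applies to toxic elements only", call. = FALSE)
  if (element != "Ni") {
    stop("no acute consumption reference exists for '", element, "'", call. = FALSE)
  }
  conc_spec <- get_concentration_dist(registry, element)
  cons <- get_consumption(registry, "acute_g_per_kgbw")
  cons_spec <- lognormal_from_moments(cons$mean, cons$sd)
  conc <- dist_sample(conc_spec, n_iter, derive_seed(seed, paste0(element, "-acute-conc")))
  rate <- dist_sample(cons_spec, n_iter, derive_seed(seed, paste0(element, "-acute-cons")))
  conc_ug <- convert_units(conc, el$concentration_units, "ug/kg")
  values <- conc_ug * rate / 1000
  new_exposure_draws(element, "acute_botanicals", "per-event", "ug/kg bw/event",
                     values, seed,
                     streams = list(concentration = conc, consumption = rate))
}
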