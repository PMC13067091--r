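#' @title Cumulative non-carcinogenic risk: THQ and hazard index
#'
#' @description
#' Target hazard quotients (THQ) scale each element's daily dose by its US
#' EPA chronic oral reference dose and by a stochastic exposure factor
#' `Ef * Ed / At`, where the exposure frequency Ef (days/year) is truncated
#' normal (mean 182.5, SD 70, range 1-365), the exposure duration Ed (years)
#' is truncated normal (mean 23, SD 10, range 1-46) and the averaging time
#' At equals `Ed * 365` days — so Ed cancels and the factor reduces to
#' `Ef / 365`, a value in (0, 1]. Under dose addition the hazard index (HI)
#' is the iteration-wise sum of THQs over Al, As (treated as inorganic), Fe,
#' Ni and Zn; Pb has no US EPA RfD and is assessed by margin of exposure
#' only.
#'
#' @name cumulative
NULL

#' The published exposure-factor model
#'
#' @return list with `ef` and `ed` truncated-normal `dist_spec`s and the
#'   averaging-time rule label.
#' @export
exposure_factor_model <- function() {
  list(
    ef = dist_spec("truncated_normal", mean = 182.5, sd = 70, lower = 1, upper = 365),
    ed = dist_spec("truncated_normal", mean = 23, sd = 10, lower = 1, upper = 46),
    at_rule = "ed_times_365"
  )
}

#' Sample the per-iteration exposure factor
#'
#' `factor_i = Ef_i * Ed_i / (Ed_i * 365) = Ef_i / 365`. Ed is sampled for
#' transparency (kept as an attribute) but cancels algebraically under the
#' averaging-time rule; results are invariant to its distribution.
#'
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param model an [exposure_factor_model()].
#' @return numeric vector of factors in (0, 1], with attributes `ef`, `ed`.
#' @export
sample_exposure_factor <- function(n_iter = 1e5, seed = 1,
                                   model = exposure_factor_model()) {
  ef <- dist_sample(model$ef, n_iter, derive_seed(seed, "exposure-factor-ef"))
  ed <- dist_sample(model$ed, n_iter, derive_seed(seed, "exposure-factor-ed"))
  factor <- ef * ed / (ed * 365)
  structure(factor, ef = ef, ed = ed)
}

#' Target hazard quotient
#'
#' `THQ_i = (dose_i / RfD) * factor_i`, with the dose and the RfD on the
#' same per-bodyweight daily basis. Draws in mg/day (essentials' baseline)
#' must first be converted with [per_bodyweight()].
#'
#' @param draws an `exposure_draws` in per-bodyweight daily units.
#' @param rfd the element's RfD reference row (mg/kg bw/day).
#' @param factor exposure-factor vector of the same length, one shared
#'   stream across all co-ingested elements.
#' @return a `metric_draws` with metric `thq`.
#' @export
thq <- function(draws, rfd, factor) {
  stopifnot(inherits(draws, "exposure_draws"))
  if (rfd$kind != "RfD") stop("reference must be an RfD", call. = FALSE)
  if (rfd$element != draws$element) stop("RfD element mismatch", call. = FALSE)
  if (length(factor) != draws$n_iter) stop("factor stream length mismatch", call. = FALSE)
  u <- parse_unit(draws$units)
  if (!u$per_bw || u$time != "day") {
    stop("THQ needs per-bodyweight daily draws; got '", draws$units,
         "' (convert with per_bodyweight())", call. = FALSE)
  }
  ref <- convert_units(rfd$value, rfd$units, draws$units)
  new_metric_draws(draws$element, draws$scenario, "thq", as.list(rfd),
                   draws$values / ref * as.numeric(factor),
                   thresholds = c(concern = 1))
}

#' Convert total daily draws to per-bodyweight doses
#'
#' Divides mg/day draws by a body weight (kg). The population body weight is
#' not part of the published input set; the package default is a 70 kg
#' adult point value.
#'
#' @param draws an `exposure_draws` in mg/day.
#' @param bw body weight in kg.
#' @return an `exposure_draws` in ug/kg bw/day.
#' @export
per_bodyweight <- function(draws, bw = 70) {
  stopifnot(inherits(draws, "exposure_draws"), bw > 0)
  u <- parse_unit(draws$units)
  if (u$per_bw) stop("draws are already per bodyweight", call. = FALSE)
  if (u$time != "day") stop("expected daily draws", call. = FALSE)
  values_mg <- convert_units(draws$values, draws$units, "mg/day")
  new_exposure_draws(draws$element, draws$scenario, "daily", "ug/kg bw/day",
                     values_mg / bw * 1000, draws$seed, streams = draws$streams)
}

#' Hazard index under dose addition
#'
#' Iteration-wise sum of THQ streams sharing one exposure-factor stream,
#' with the decomposition of the mean HI into per-element shares.
#'
#' @param thqs list of `metric_draws` with metric `thq`, same `n_iter`.
#' @return a `hazard_decomposition`: list with `hi` (numeric vector),
#'   `thqs`, `shares` (named, sums to 1) and `summary` data.frame.
#' @export
hazard_index <- function(thqs) {
  stopifnot(is.list(thqs), length(thqs) >= 1)
  if (!all(vapply(thqs, function(x) inherits(x, "metric_draws") && x$metric == "thq",
                  logical(1)))) {
    stop("inputs must be THQ metric draws", call. = FALSE)
  }
  n <- unique(vapply(thqs, `[[`, 0L, "n_iter"))
  if (length(n) != 1) stop("THQ streams differ in length", call. = FALSE)
  names(thqs) <- vapply(thqs, `[[`, "", "element")
  hi <- Reduce(`+`, lapply(thqs, `[[`, "values"))
  means <- vapply(thqs, function(x) mean(x$values), 0)
  shares <- means / sum(means)
  summary <- do.call(rbind, c(
    lapply(names(thqs), function(el) cbind(component = el, summarize_draws(thqs[[el]]))),
    list(cbind(component = "HI", summarize_draws(hi)))
  ))
  structure(list(hi = hi, thqs = thqs, shares = shares, summary = summary),
            class = "hazard_decomposition")
}

#' @export
print.hazard_decomposition <- function(x, ...) {
  cat("<hazard_decomposition>", length(x$thqs), "elements\n")
  print(x$summary, row.names = FALSE)
  cat("mean-HI shares (%):",
      paste(names(x$shares), sprintf("%.1f", 100 * x$shares), collapse = ", "), "\n")
  invisible(x)
}

#' Run the cumulative risk assessment
#'
#' Builds THQ streams for Al, As, Fe, Ni and Zn under the requested scenario
#' and sums them into the hazard index. In the botanicals-only scenario all
#' five doses come from the body-weight-normalized chronic consumption
#' pattern; in the combined scenario each element additionally receives its
#' baseline intake (Fe and Zn baseline mg/day doses divided by `bw`). One
#' exposure-factor stream is shared across elements within an iteration.
#'
#' @param registry an `rba_registry`.
#' @param scenario `"botanicals"` or `"combined"`.
#' @param n_iter iterations.
#' @param seed root seed.
#' @param bw body weight (kg) for converting total daily baseline doses.
#' @param elements elements entering the hazard index.
#' @return a `hazard_decomposition`.
#' @export
cumulative_risk <- function(registry, scenario = c("botanicals", "combined"),
                            n_iter = 1e5, seed = 1, bw = 70,
                            elements = c("Al", "As", "Fe", "Ni", "Zn")) {
  scenario <- match.arg(scenario)
  factor <- sample_exposure_factor(n_iter, seed)
  thqs <- lapply(elements, function(el) {
    rfd <- get_reference(registry, el, "RfD")
    dose <- cumulative_dose(registry, el, scenario, n_iter, seed, bw)
    thq(dose, rfd, factor)
  })
  hazard_index(thqs)
}

# Per-bodyweight daily dose of one element for the cumulative assessment.
cumulative_dose <- function(registry, element, scenario, n_iter, seed, bw) {
  el <- get_element(registry, element)
  conc_spec <- get_concentration_dist(registry, element)
  cons <- get_consumption(registry, "chronic_g_per_kgbw_day")
  cons_spec <- lognormal_from_moments(cons$mean, cons$sd)
  conc <- dist_sample(conc_spec, n_iter, derive_seed(seed, paste0(element, "-cum-conc")))
  rate <- dist_sample(cons_spec, n_iter, derive_seed(seed, paste0(element, "-cum-cons")))
  conc_ug <- convert_units(conc, el$concentration_units, "ug/kg")
  bot <- new_exposure_draws(element, "botanicals", "daily", "ug/kg bw/day",
                            conc_ug * rate / 1000, seed,
                            streams = list(concentration = conc, consumption = rate))
  if (scenario == "botanicals") return(bot)
  base <- simulate_baseline(registry, element, n_iter, seed)
  if (!parse_unit(base$units)$per_bw) base <- per_bodyweight(base, bw)
  combine_exposure(base, bot)
}
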