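#' @title Benefit and risk metrics
#'
#' @description
#' Per-iteration transforms of exposure draws: percentage contribution to a
#' dietary reference value or tolerable intake (benefit/risk share), margin
#' of exposure against a BMDL or LOAEL reference point, and exceedance
#' fractions against interpretation thresholds (MOE < 10 for BMDL-based
#' concern, < 30 for Ni sensitization, < 1 for exposure above the reference
#' point).
#'
#' @name metrics
NULL

new_metric_draws <- function(element, scenario, metric, reference, values,
                             thresholds = NULL) {
  structure(
    list(element = element, scenario = scenario, metric = metric,
         reference = reference, values = as.numeric(values),
         thresholds = thresholds, n_iter = length(values)),
    class = "metric_draws"
  )
}

#' @export
print.metric_draws <- function(x, ...) {
  s <- summarize_draws(x)
  cat("<metric_draws> ", x$element, " / ", x$scenario, " / ", x$metric,
      " vs ", x$reference$kind, " (", x$reference$endpoint, ")\n", sep = "")
  cat(sprintf("  mean %.4g  sd %.4g  median %.4g  P5-P95 %.4g-%.4g\n",
              s$mean, s$sd, s$median, s$p5, s$p95))
  invisible(x)
}

.basis_of_units <- function(units) {
  u <- parse_unit(units)
  switch(u$time, day = "daily", week = "weekly", event = "per-event",
         stop("units '", units, "' carry no intake basis", call. = FALSE))
}

# reference value expressed in the draws' units, with basis check
.reference_in_draw_units <- function(draws, reference) {
  ref_basis <- .basis_of_units(reference$units)
  if (ref_basis != draws$basis) {
    stop("basis mismatch: draws are ", draws$basis, " but the ",
         reference$kind, " is ", ref_basis, call. = FALSE)
  }
  convert_units(reference$value, reference$units, draws$units)
}

#' Percentage contribution to a reference value
#'
#' Per-iteration `100 * intake / reference`, for benefit references (AI,
#' PRI, UL) and tolerable intakes (TDI, TWI) alike. The reference is
#' converted to the draws' units; a daily/weekly basis mismatch (e.g. daily
#' Al draws against the weekly Al tolerable intake) is an error.
#'
#' @param draws an `exposure_draws`.
#' @param reference a one-row reference from [get_reference()].
#' @return a `metric_draws` with metric `pct_drv`, `pct_tdi` or `pct_twi`.
#' @export
percent_reference <- function(draws, reference) {
  stopifnot(inherits(draws, "exposure_draws"))
  if (reference$element != draws$element) stop("reference element mismatch", call. = FALSE)
  ref <- .reference_in_draw_units(draws, reference)
  metric <- switch(reference$kind, TDI = "pct_tdi", TWI = "pct_twi", "pct_drv")
  new_metric_draws(draws$element, draws$scenario, metric, as.list(reference),
                   100 * draws$values / ref)
}

#' Total percentage contribution from baseline plus botanicals
#'
#' Iteration-wise additive version: the total percentage is exactly the sum
#' of the two component percentages.
#'
#' @param baseline,botanicals `exposure_draws` as in [combine_exposure()].
#' @param reference a one-row reference from [get_reference()].
#' @return a `metric_draws` for the combined scenario.
#' @export
percent_drv_total <- function(baseline, botanicals, reference) {
  combined <- combine_exposure(baseline, botanicals)
  percent_reference(combined, reference)
}

#' Margin of exposure
#'
#' Per-iteration `reference / intake` against a BMDL (chronic) or LOAEL
#' (per-event) reference point. Standard interpretation thresholds are
#' attached as annotations: 10 for BMDL-based concern, 30 for Ni
#' sensitization, 1 for exposure exceeding the reference point.
#'
#' @param draws an `exposure_draws`.
#' @param reference a BMDL or LOAEL reference row.
#' @return a `metric_draws` with metric `moe`.
#' @export
margin_of_exposure <- function(draws, reference) {
  stopifnot(inherits(draws, "exposure_draws"))
  if (!reference$kind %in% c("BMDL", "LOAEL")) {
    stop("margin of exposure needs a BMDL or LOAEL reference", call. = FALSE)
  }
  if (reference$element != draws$element) stop("reference element mismatch", call. = FALSE)
  ref <- .reference_in_draw_units(draws, reference)
  thresholds <- if (reference$kind == "LOAEL") c(concern = 30) else c(concern = 10, exceeds_rp = 1)
  new_metric_draws(draws$element, draws$scenario, "moe", as.list(reference),
                   ref / draws$values, thresholds = thresholds)
}

#' Fraction of iterations beyond a cutpoint
#'
#' Strict inequality on the stated side (the boundary is a measure-zero
#' event under the continuous exposure models).
#'
#' @param metric a `metric_draws` (or `exposure_draws`).
#' @param cut cutpoint.
#' @param direction `"below"` or `"above"`.
#' @return the fraction in `[0, 1]`.
#' @export
exceedance_fraction <- function(metric, cut, direction = c("below", "above")) {
  direction <- match.arg(direction)
  values <- metric$values
  if (!length(values)) stop("empty draw vector", call. = FALSE)
  if (direction == "below") mean(values < cut) else mean(values > cut)
}

#' Five-number summary of a draw vector
#'
#' Mean, SD, median and the 5th/95th percentiles (linear interpolation of
#' order statistics, `stats::quantile` type 7) — the reporting format used
#' for every exposure and metric distribution.
#'
#' @param x an `exposure_draws`, `metric_draws` or numeric vector.
#' @return one-row data.frame: mean, sd, median, p5, p95.
#' @export
summarize_draws <- function(x) {
  values <- if (is.numeric(x)) x else x$values
  if (!length(values)) stop("empty draw vector", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  data.frame(mean = mean(values), sd = stats::sd(values),
             median = q[2], p5 = q[1], p95 = q[3])
}
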