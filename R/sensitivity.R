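#' @title Sensitivity analysis by Spearman rank correlation
#'
#' @description
#' Attributes variability in a simulated output (an intake or a derived
#' metric) to the modeled input streams by the Spearman rank correlation
#' computed on paired iterations — Pearson correlation of midranks, with
#' average ranks under ties, which is invariant to monotone transforms of
#' either variable.
#'
#' @name sensitivity
NULL

#' Rank-correlation sensitivity of an output to its input streams
#'
#' Inputs and output must come from the same Monte Carlo iterations (e.g.
#' the `$streams` carried by botanicals `exposure_draws`), so the pairing is
#' exact.
#'
#' @param inputs named list of numeric vectors (the input streams).
#' @param output an `exposure_draws`, `metric_draws` or numeric vector of
#'   the same length.
#' @return a `sensitivity_report`: data.frame with columns `input`, `rho`,
#'   `n_iter`. A zero-variance input yields `NA` with a warning.
#' @examples
#' reg <- load_registry()
#' edi <- simulate_botanicals_edi(reg, "As", n_iter = 1000, seed = 1)
#' moe <- margin_of_exposure(edi, get_reference(reg, "As", "BMDL"))
#' spearman_sensitivity(edi$streams, moe)
#' @export
spearman_sensitivity <- function(inputs, output) {
  stopifnot(is.list(inputs), length(inputs) >= 1, !is.null(names(inputs)))
  out <- if (is.numeric(output)) output else output$values
  n <- length(out)
  rho <- vapply(names(inputs), function(nm) {
    x <- inputs[[nm]]
    if (length(x) != n) {
      stop("input '", nm, "' length ", length(x), " != output length ", n,
           call. = FALSE)
    }
    if (stats::sd(x) == 0 || stats::sd(out) == 0) {
      warning("zero-variance stream; rho undefined for '", nm, "'", call. = FALSE)
      return(NA_real_)
    }
    stats::cor(x, out, method = "spearman")
  }, 0)
  structure(
    data.frame(input = names(inputs), rho = unname(rho), n_iter = n,
               stringsAsFactors = FALSE),
    class = c("sensitivity_report", "data.frame")
  )
}
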