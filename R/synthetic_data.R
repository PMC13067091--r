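#' @title Synthetic concentration tables
#'
#' @description
#' The raw per-extract element measurements behind the published summary
#' statistics are not public. This module generates synthetic concentration
#' matrices (default 25 botanical products x 10 elements) with the same
#' statistical structure the analysis assumes: each element column is an
#' independent draw from its fitted family (lognormal or exponential),
#' parameterized by moment matching of the published mean and SD. The tables
#' make every downstream stage testable end to end; they are synthetic
#' stand-ins, not the measured data.
#'
#' @name synthetic_data
NULL

#' Generate a synthetic concentration table
#'
#' Each element column is sampled independently from its registry family:
#' lognormal columns via [lognormal_from_moments()], exponential columns with
#' rate `1/mean`. Columns are in the element's canonical concentration units
#' (mg or ug per kg of dry extract) and strictly positive.
#'
#' @param registry an `rba_registry` (supplies families, moments, units and
#'   default row labels).
#' @param n_samples number of rows; when 25 (the default), rows are labelled
#'   with the registry's commercial product names.
#' @param seed integer seed; per-element sub-streams are derived from it.
#' @return a `concentration_table`: data.frame with a `product` column and
#'   one column per element; element units in the `units` attribute.
#' @examples
#' reg <- load_registry()
#' tab <- generate_concentrations(reg, n_samples = 25, seed = 1)
#' @export
generate_concentrations <- function(registry, n_samples = 25, seed = 1) {
  stopifnot(inherits(registry, "rba_registry"), n_samples >= 1)
  syms <- registry$elements$symbol
  cols <- lapply(syms, function(sym) {
    spec <- get_concentration_dist(registry, sym)
    dist_sample(spec, n_samples, derive_seed(seed, paste0("conc-table-", sym)))
  })
  names(cols) <- syms
  labels <- if (n_samples == length(registry$products)) {
    registry$products
  } else {
    sprintf("synthetic_%03d", seq_len(n_samples))
  }
  tab <- data.frame(product = labels, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  units <- stats::setNames(registry$elements$concentration_units, syms)
  structure(tab, units = units, seed = seed, class = c("concentration_table", "data.frame"))
}

#' Write / read a concentration table as CSV
#'
#' The CSV carries a `# units:` metadata banner so the table round-trips
#' losslessly. The reader validates structure and strict positivity and
#' rejects malformed cells, naming the row and column.
#'
#' @param table a `concentration_table`.
#' @param path CSV path.
#' @return `write_concentrations`: invisibly, `path`.
#' @export
write_concentrations <- function(table, path) {
  stopifnot(inherits(table, "concentration_table"))
  units <- attr(table, "units")
  banner <- paste0("# units: ", paste(names(units), units, sep = "=", collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(banner, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentrations
#' @return `read_concentrations`: the `concentration_table`.
#' @export
read_concentrations <- function(path) {
  lines <- readLines(path, n = 1)
  if (!grepl("^# units:", lines)) stop("missing units banner in ", path, call. = FALSE)
  spec <- sub("^# units:\\s*", "", lines)
  pairs <- strsplit(strsplit(spec, ";\\s*")[[1]], "=", fixed = TRUE)
  units <- stats::setNames(vapply(pairs, `[[`, "", 2), vapply(pairs, `[[`, "", 1))
  tab <- utils::read.csv(path, skip = 1, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "product") stop("first column must be 'product'", call. = FALSE)
  elems <- setdiff(names(tab), "product")
  if (!setequal(elems, names(units))) {
    stop("column/units mismatch in ", path, call. = FALSE)
  }
  for (el in elems) {
    bad <- which(!is.finite(tab[[el]]) | tab[[el]] <= 0)
    if (length(bad)) {
      stop("invalid concentration at row ", bad[1], " ('", tab$product[bad[1]],
           "'), column ", el, ": must be a positive number", call. = FALSE)
    }
  }
  structure(tab, units = units[elems], class = c("concentration_table", "data.frame"))
}
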