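#' @title Reference-data registry
#'
#' @description
#' The registry is the single source of every constant the pipeline uses:
#' element definitions, concentration summaries of botanical extracts,
#' baseline dietary intake of the adult population, botanical consumption
#' patterns, and all benefit/risk anchors (DRVs, HBGVs, reference points and
#' US EPA RfDs). It is loaded from a bundled YAML config, unit-canonicalized
#' and validated for completeness at load time.
#'
#' @name registry
NULL

.expected_elements <- c("Ca", "K", "P", "Mg", "Fe", "Zn", "Al", "Ni", "As", "Pb")

# (element, kind, endpoint) triples that must be present for the published
# analyses to run.
.required_references <- list(
  c("P", "AI", "adequacy"),
  c("Al", "TWI", "neurotoxicity"),
  c("Ni", "TDI", "reproductive and developmental toxicity"),
  c("Ni", "LOAEL", "systemic contact dermatitis"),
  c("As", "BMDL", "skin cancer"),
  c("Pb", "BMDL", "cardiovascular effects"),
  c("Pb", "BMDL", "nephrotoxicity"),
  c("Al", "RfD", "chronic non-carcinogenic"),
  c("As", "RfD", "chronic non-carcinogenic"),
  c("Fe", "RfD", "chronic non-carcinogenic"),
  c("Ni", "RfD", "chronic non-carcinogenic"),
  c("Zn", "RfD", "chronic non-carcinogenic")
)

#' Path of the bundled registry config
#' @return filesystem path to the packaged YAML config.
#' @export
default_registry_config <- function() {
  system.file("extdata", "registry.yaml", package = "botanrisk", mustWork = TRUE)
}

#' Load and validate the reference-data registry
#'
#' Reads the structured config, canonicalizes every value to its element's
#' canonical units and validates completeness: exactly the ten study elements,
#' the three consumption patterns, a baseline intake per element, and every
#' health-reference triple needed downstream. Any missing or malformed entry
#' aborts the load with a message naming the offending entry.
#'
#' @param config_path path to a registry YAML file; defaults to the bundled
#'   config.
#' @return an object of class `rba_registry` with components `elements`,
#'   `concentrations`, `baseline`, `references`, `consumption` (data.frames)
#'   and `products` (character), plus a `config_digest` attribute.
#' @examples
#' reg <- load_registry()
#' get_reference(reg, "As", "BMDL", "skin cancer")$value # 0.06 ug/kg bw/day
#' @export
load_registry <- function(config_path = default_registry_config()) {
  if (!file.exists(config_path)) {
    stop("registry config not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  for (sec in c("elements", "concentrations", "baseline_intake",
                "consumption", "health_references", "products")) {
    if (is.null(cfg[[sec]])) stop("config is missing section '", sec, "'", call. = FALSE)
  }

  elements <- do.call(rbind, lapply(names(cfg$elements), function(sym) {
    e <- cfg$elements[[sym]]
    data.frame(symbol = sym, class = e$class,
               concentration_units = e$concentration_units,
               intake_units = e$intake_units, stringsAsFactors = FALSE)
  }))
  missing <- setdiff(.expected_elements, elements$symbol)
  extra <- setdiff(elements$symbol, .expected_elements)
  if (length(missing)) stop("missing element(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra)) stop("unexpected element(s): ", paste(extra, collapse = ", "), call. = FALSE)
  if (!all(elements$class %in% c("essential", "toxic"))) {
    stop("element class must be 'essential' or 'toxic'", call. = FALSE)
  }

  conc <- do.call(rbind, lapply(names(cfg$concentrations), function(sym) {
    cc <- cfg$concentrations[[sym]]
    data.frame(element = sym, family = cc$family, mean = cc$mean, sd = cc$sd,
               median = cc$median %||% NA_real_, p5 = cc$p5 %||% NA_real_,
               p95 = cc$p95 %||% NA_real_, units = cc$units,
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(conc))) {
    row <- conc[i, ]
    eu <- elements$concentration_units[elements$symbol == row$element]
    if (length(eu) != 1 || !units_compatible(row$units, eu)) {
      stop("concentration units for ", row$element, " not canonicalizable", call. = FALSE)
    }
    for (col in c("mean", "sd", "median", "p5", "p95")) {
      conc[i, col] <- convert_units(row[[col]], row$units, eu)
    }
    conc$units[i] <- eu
    if (!is.na(conc$median[i]) && !is.na(conc$p5[i]) && !is.na(conc$p95[i]) &&
        !(conc$p5[i] <= conc$median[i] && conc$median[i] <= conc$p95[i])) {
      stop("percentile ordering violated for ", row$element, call. = FALSE)
    }
    if (conc$mean[i] <= 0) stop("nonpositive mean concentration for ", row$element, call. = FALSE)
  }
  if (!setequal(conc$element, .expected_elements)) {
    stop("concentration summaries must cover all 10 elements", call. = FALSE)
  }

  baseline <- do.call(rbind, lapply(names(cfg$baseline_intake), function(sym) {
    b <- cfg$baseline_intake[[sym]]
    data.frame(element = sym, mean = b$mean, sd = b$sd, units = b$units,
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(baseline))) {
    sym <- baseline$element[i]
    iu <- elements$intake_units[elements$symbol == sym]
    if (length(iu) != 1 || !units_compatible(baseline$units[i], iu)) {
      stop("baseline intake units for ", sym, " not canonicalizable", call. = FALSE)
    }
    baseline$mean[i] <- convert_units(baseline$mean[i], baseline$units[i], iu)
    baseline$sd[i] <- convert_units(baseline$sd[i], baseline$units[i], iu)
    baseline$units[i] <- iu
  }
  if (!setequal(baseline$element, .expected_elements)) {
    stop("baseline intake must cover all 10 elements", call. = FALSE)
  }

  refs <- do.call(rbind, lapply(cfg$health_references, function(r) {
    data.frame(element = r$element, kind = r$kind, value = r$value,
               units = r$units, endpoint = r$endpoint, basis = r$basis,
               note = r$note %||% "", stringsAsFactors = FALSE)
  }))
  key <- paste(refs$element, refs$kind, refs$endpoint, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate health reference: (",
         gsub("\\|", ", ", key[duplicated(key)][1]), ")", call. = FALSE)
  }
  for (tr in .required_references) {
    if (!any(refs$element == tr[1] & refs$kind == tr[2] & refs$endpoint == tr[3])) {
      stop("missing health reference (", paste(tr, collapse = ", "), ")", call. = FALSE)
    }
  }
  if (any(refs$value <= 0)) stop("health reference values must be positive", call. = FALSE)
  for (u in unique(refs$units)) parse_unit(u) # fail fast on unit typos

  cons <- do.call(rbind, lapply(names(cfg$consumption), function(mode) {
    cc <- cfg$consumption[[mode]]
    data.frame(mode = mode, mean = cc$mean, sd = cc$sd, units = cc$units,
               stringsAsFactors = FALSE)
  }))
  needed_modes <- c("chronic_total_g_per_day", "chronic_g_per_kgbw_day",
                    "acute_g_per_kgbw")
  if (!all(needed_modes %in% cons$mode)) {
    stop("consumption patterns must include: ",
         paste(setdiff(needed_modes, cons$mode), collapse = ", "), call. = FALSE)
  }

  products <- as.character(cfg$products)

  reg <- structure(
    list(elements = elements, concentrations = conc, baseline = baseline,
         references = refs, consumption = cons, products = products),
    class = "rba_registry",
    config_path = config_path,
    config_digest = unname(tools::md5sum(config_path))
  )
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rba_registry <- function(x, ...) {
  cat("<rba_registry>", nrow(x$elements), "elements,",
      nrow(x$references), "health references,",
      nrow(x$consumption), "consumption patterns,",
      length(x$products), "products\n")
  invisible(x)
}

#' Registry lookups
#'
#' @param registry an `rba_registry`.
#' @param element element symbol.
#' @param kind reference kind (AI, PRI, UL, TDI, TWI, BMDL, LOAEL, RfD).
#' @param endpoint optional endpoint label, required when the
#'   (element, kind) pair is ambiguous (the two Pb BMDLs).
#' @return `get_reference`: one-row data.frame (element, kind, value, units,
#'   endpoint, basis).
#' @export
get_reference <- function(registry, element, kind, endpoint = NULL) {
  stopifnot(inherits(registry, "rba_registry"))
  r <- registry$references
  hit <- r$element == element & r$kind == kind
  if (!is.null(endpoint)) hit <- hit & r$endpoint == endpoint
  if (sum(hit) == 0) {
    stop("no health reference (", element, ", ", kind,
         if (!is.null(endpoint)) paste0(", ", endpoint), ")", call. = FALSE)
  }
  if (sum(hit) > 1) {
    stop("ambiguous reference (", element, ", ", kind, "): give an endpoint among: ",
         paste(r$endpoint[hit], collapse = "; "), call. = FALSE)
  }
  r[hit, , drop = FALSE]
}

#' @rdname get_reference
#' @return `get_element`: one-row data.frame from the element table.
#' @export
get_element <- function(registry, element) {
  stopifnot(inherits(registry, "rba_registry"))
  e <- registry$elements[registry$elements$symbol == element, , drop = FALSE]
  if (nrow(e) != 1) stop("unknown element '", element, "'", call. = FALSE)
  e
}

#' @rdname get_reference
#' @return `get_baseline_moments`: one-row data.frame (mean, sd, units).
#' @export
get_baseline_moments <- function(registry, element) {
  stopifnot(inherits(registry, "rba_registry"))
  b <- registry$baseline[registry$baseline$element == element, , drop = FALSE]
  if (nrow(b) != 1) stop("no baseline intake for '", element, "'", call. = FALSE)
  b
}

#' @rdname get_reference
#' @param mode consumption mode: `"chronic_total_g_per_day"`,
#'   `"chronic_g_per_kgbw_day"` or `"acute_g_per_kgbw"`.
#' @return `get_consumption`: one-row data.frame (mean, sd, units).
#' @export
get_consumption <- function(registry, mode) {
  stopifnot(inherits(registry, "rba_registry"))
  cc <- registry$consumption[registry$consumption$mode == mode, , drop = FALSE]
  if (nrow(cc) != 1) stop("no consumption pattern '", mode, "'", call. = FALSE)
  cc
}

#' Concentration sampling distribution for an element
#'
#' Builds the element's probabilistic concentration model from the registry
#' summary: lognormal columns by moment matching of mean and SD, exponential
#' columns with rate `1/mean` (the exponential MLE given only a mean).
#'
#' @param registry an `rba_registry`.
#' @param element element symbol.
#' @return a `dist_spec` in the element's canonical concentration units.
#' @export
get_concentration_dist <- function(registry, element) {
  stopifnot(inherits(registry, "rba_registry"))
  cc <- registry$concentrations[registry$concentrations$element == element, , drop = FALSE]
  if (nrow(cc) != 1) stop("no concentration summary for '", element, "'", call. = FALSE)
  switch(cc$family,
    lognormal = lognormal_from_moments(cc$mean, cc$sd),
    exponential = dist_spec("exponential", rate = 1 / cc$mean),
    stop("unsupported concentration family '", cc$family, "'", call. = FALSE)
  )
}

#' Serialize the registry
#'
#' Writes the full canonicalized registry to CSV files (one per table) or a
#' single JSON document, for review or downstream tooling.
#'
#' @param registry an `rba_registry`.
#' @param path output directory (CSV) or file ending in `.json`.
#' @return invisibly, the paths written.
#' @export
dump_registry <- function(registry, path) {
  stopifnot(inherits(registry, "rba_registry"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      registry[c("elements", "concentrations", "baseline", "references",
                 "consumption", "products")],
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (tab in c("elements", "concentrations", "baseline", "references", "consumption")) {
    f <- file.path(path, paste0("registry_", tab, ".csv"))
    utils::write.csv(registry[[tab]], f, row.names = FALSE)
    out <- c(out, f)
  }
  f <- file.path(path, "registry_products.csv")
  utils::write.csv(data.frame(product = registry$products), f, row.names = FALSE)
  invisible(c(out, f))
}
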