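#' @title End-to-end study runs and reporting
#'
#' @description
#' `run_full_study()` executes the whole pipeline — exposure under all
#' scenarios, benefit and risk metrics, exceedance fractions, cumulative
#' risk and sensitivity — from one root seed, and returns a bundle of tidy
#' data.frames mirroring the published summary-table layout. `write_bundle()`
#' renders the bundle as CSV files plus one JSON document with full run
#' provenance (seed, iteration count, package version, registry digest).
#'
#' @name reporting
NULL

# the reference used for each element's percentage metric
.primary_percent_ref <- list(
  Ca = c("PRI", "adequacy"), K = c("AI", "adequacy"), Mg = c("AI", "adequacy"),
  P = c("AI", "adequacy"), Fe = c("PRI", "adequacy"), Zn = c("PRI", "adequacy"),
  Al = c("TWI", "neurotoxicity"),
  Ni = c("TDI", "reproductive and developmental toxicity")
)

.summary_row <- function(obj, element, scenario, metric, units, extra = list()) {
  s <- summarize_draws(obj)
  base <- data.frame(element = element, scenario = scenario, metric = metric,
                     units = units, stringsAsFactors = FALSE)
  if (length(extra)) cbind(base, s, as.data.frame(extra)) else cbind(base, s)
}

#' Run the complete risk-benefit study
#'
#' One call reproduces every published result surface: per-element intake
#' summaries under the baseline, botanicals-only, combined and (Ni) acute
#' scenarios; percentage contributions to reference values; margins of
#' exposure with threshold exceedance fractions; the cumulative hazard
#' index under both scenarios; and the rank-correlation sensitivity of the
#' botanicals-only outputs. All randomness derives from `seed`.
#'
#' @param registry an `rba_registry`.
#' @param n_iter Monte Carlo iterations per stream (published design:
#'   100 000).
#' @param seed root seed.
#' @param bw adult body weight (kg) for per-bodyweight conversion of total
#'   daily doses.
#' @return an `rba_study` list: `meta`, `exposure`, `metrics`,
#'   `exceedance`, `cumulative`, `sensitivity`.
#' @export
run_full_study <- function(registry = load_registry(), n_iter = 1e5,
                           seed = 42, bw = 70) {
  stopifnot(inherits(registry, "rba_registry"))
  syms <- registry$elements$symbol

  exposure <- list()
  metrics <- list()
  exceed <- list()
  sens <- list()

  report_units <- function(el, draws) draws$units

  for (el in syms) {
    base <- simulate_baseline(registry, el, n_iter, seed)
    bot <- simulate_botanicals_edi(registry, el, n_iter, seed)
    comb <- combine_exposure(base, bot)

    # Al is reported and referenced on a weekly basis
    base_r <- if (el == "Al") weekly_from_daily(base) else base
    bot_r <- if (el == "Al") weekly_from_daily(bot) else bot
    comb_r <- if (el == "Al") weekly_from_daily(comb) else comb

    exposure[[length(exposure) + 1]] <-
      .summary_row(base_r, el, "baseline", "intake", base_r$units,
                   extra = list(botanical_share_mean = NA_real_,
                                botanical_share_sd = NA_real_))
    exposure[[length(exposure) + 1]] <-
      .summary_row(bot_r, el, "botanicals", "intake", bot_r$units,
                   extra = list(botanical_share_mean = NA_real_,
                                botanical_share_sd = NA_real_))
    share <- comb$streams$botanical_share
    exposure[[length(exposure) + 1]] <-
      .summary_row(comb_r, el, "combined", "intake", comb_r$units,
                   extra = list(botanical_share_mean = mean(share),
                                botanical_share_sd = stats::sd(share)))

    pr <- .primary_percent_ref[[el]]
    if (!is.null(pr)) {
      ref <- get_reference(registry, el, pr[1], pr[2])
      for (sc in c("baseline", "botanicals", "combined")) {
        d <- switch(sc, baseline = base_r, botanicals = bot_r, combined = comb_r)
        m <- percent_reference(d, ref)
        metrics[[length(metrics) + 1]] <-
          .summary_row(m, el, sc, m$metric, "%",
                       extra = list(reference = ref$kind, endpoint = ref$endpoint))
      }
    }
    if (el %in% c("As", "Pb")) {
      refs <- registry$references
      bmdls <- refs[refs$element == el & refs$kind == "BMDL", , drop = FALSE]
      for (i in seq_len(nrow(bmdls))) {
        ref <- bmdls[i, , drop = FALSE]
        for (sc in c("baseline", "botanicals", "combined")) {
          d <- switch(sc, baseline = base, botanicals = bot, combined = comb)
          m <- margin_of_exposure(d, ref)
          metrics[[length(metrics) + 1]] <-
            .summary_row(m, el, sc, "moe", "",
                         extra = list(reference = ref$kind, endpoint = ref$endpoint))
          for (cut in m$thresholds) {
            exceed[[length(exceed) + 1]] <- data.frame(
              element = el, scenario = sc, metric = "moe",
              endpoint = ref$endpoint, cut = cut, direction = "below",
              fraction = exceedance_fraction(m, cut, "below"),
              stringsAsFactors = FALSE)
          }
        }
      }
    }

    # sensitivity of the botanicals-only output to its input streams
    out <- if (el == "As") {
      margin_of_exposure(bot, get_reference(registry, el, "BMDL", "skin cancer"))
    } else {
      bot
    }
    sr <- spearman_sensitivity(bot$streams, out)
    sr$element <- el
    sr$output <- if (el == "As") "moe_skin_cancer" else "botanicals_edi"
    sens[[length(sens) + 1]] <- sr
  }

  # acute Ni
  acute <- simulate_acute(registry, "Ni", n_iter, seed)
  exposure[[length(exposure) + 1]] <-
    .summary_row(acute, "Ni", "acute_botanicals", "intake", acute$units,
                 extra = list(botanical_share_mean = NA_real_,
                              botanical_share_sd = NA_real_))
  loael <- get_reference(registry, "Ni", "LOAEL")
  moe_acute <- margin_of_exposure(acute, loael)
  metrics[[length(metrics) + 1]] <-
    .summary_row(moe_acute, "Ni", "acute_botanicals", "moe", "",
                 extra = list(reference = "LOAEL", endpoint = loael$endpoint))
  exceed[[length(exceed) + 1]] <- data.frame(
    element = "Ni", scenario = "acute_botanicals", metric = "moe",
    endpoint = loael$endpoint, cut = 30, direction = "below",
    fraction = exceedance_fraction(moe_acute, 30, "below"),
    stringsAsFactors = FALSE)

  # cumulative hazard index
  cum <- lapply(c(botanicals = "botanicals", combined = "combined"), function(sc) {
    hd <- cumulative_risk(registry, sc, n_iter, seed, bw)
    list(summary = cbind(scenario = sc, hd$summary),
         shares = data.frame(scenario = sc, element = names(hd$shares),
                             share = unname(hd$shares), stringsAsFactors = FALSE))
  })

  structure(list(
    meta = list(seed = seed, n_iter = n_iter, bw = bw,
                package_version = as.character(utils::packageVersion("botanrisk")),
                config_digest = attr(registry, "config_digest"),
                timestamp = format(Sys.time(), tz = "UTC")),
    exposure = do.call(rbind, exposure),
    metrics = do.call(rbind, metrics),
    exceedance = do.call(rbind, exceed),
    cumulative = list(
      summary = do.call(rbind, lapply(cum, `[[`, "summary")),
      shares = do.call(rbind, lapply(cum, `[[`, "shares"))
    ),
    sensitivity = do.call(rbind, sens)
  ), class = "rba_study")
}

#' @export
print.rba_study <- function(x, ...) {
  cat("<rba_study> seed", x$meta$seed, "| n_iter", x$meta$n_iter, "\n")
  cat(" exposure rows:", nrow(x$exposure),
      "| metric rows:", nrow(x$metrics),
      "| exceedance rows:", nrow(x$exceedance), "\n")
  invisible(x)
}

#' Write a study bundle to disk
#'
#' @param study an `rba_study` from [run_full_study()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_bundle <- function(study, out_dir) {
  stopifnot(inherits(study, "rba_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  w(study$exposure, "exposure_summary.csv")
  w(study$metrics, "metric_summary.csv")
  w(study$exceedance, "exceedance_fractions.csv")
  w(study$cumulative$summary, "cumulative_summary.csv")
  w(study$cumulative$shares, "cumulative_shares.csv")
  w(study$sensitivity, "sensitivity.csv")
  jf <- file.path(out_dir, "study.json")
  jsonlite::write_json(
    list(meta = study$meta, exposure = study$exposure, metrics = study$metrics,
         exceedance = study$exceedance,
         cumulative_summary = study$cumulative$summary,
         cumulative_shares = study$cumulative$shares,
         sensitivity = study$sensitivity),
    jf, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, jf))
}
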