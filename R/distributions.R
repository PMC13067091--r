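#' @title Parametric distribution toolkit
#'
#' @description
#' Light S3 wrapper around the parametric families used by the exposure
#' model: normal, lognormal, exponential, Weibull, Pareto and truncated
#' normal. A `dist_spec` holds a family tag and its parameters; `dist_sample()`
#' draws seeded reproducible samples, `dist_cdf()`/`dist_quantile()` give the
#' closed forms used as Monte Carlo oracles, `fit_mle()` fits a family to data
#' by maximum likelihood and `select_by_aic()` ranks candidate fits.
#'
#' @name distributions
NULL

.dist_families <- c("normal", "lognormal", "exponential", "weibull",
                    "pareto", "truncated_normal")

.dist_npar <- c(normal = 2, lognormal = 2, exponential = 1, weibull = 2,
                pareto = 2, truncated_normal = 2)

#' Construct a distribution specification
#'
#' @param family one of `"normal"`, `"lognormal"`, `"exponential"`,
#'   `"weibull"`, `"pareto"`, `"truncated_normal"`.
#' @param ... named parameters: `mean`,`sd` (normal); `meanlog`,`sdlog`
#'   (lognormal); `rate` (exponential); `shape`,`scale` (weibull);
#'   `xm`,`alpha` (pareto); `mean`,`sd`,`lower`,`upper` (truncated_normal).
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, .dist_families)
  params <- list(...)
  req <- switch(family,
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    exponential = "rate",
    weibull = c("shape", "scale"),
    pareto = c("xm", "alpha"),
    truncated_normal = c("mean", "sd", "lower", "upper")
  )
  missing <- setdiff(req, names(params))
  if (length(missing)) {
    stop(family, " spec requires parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- params[req]
  pos <- switch(family,
    normal = "sd", lognormal = "sdlog", exponential = "rate",
    weibull = c("shape", "scale"), pareto = c("xm", "alpha"),
    truncated_normal = "sd"
  )
  for (p in pos) {
    if (!is.finite(params[[p]]) || params[[p]] <= 0) {
      stop(family, " parameter '", p, "' must be positive", call. = FALSE)
    }
  }
  if (family == "lognormal" && params$sdlog < 0) {
    stop("sdlog must be nonnegative", call. = FALSE)
  }
  if (family == "truncated_normal" && params$lower >= params$upper) {
    stop("truncated_normal requires lower < upper", call. = FALSE)
  }
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$family, "(",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Lognormal specification from arithmetic moments
#'
#' Moment matching: given an arithmetic mean m and standard deviation s, the
#' lognormal with `sdlog^2 = log(1 + (s/m)^2)` and
#' `meanlog = log(m) - sdlog^2/2` has analytic mean m and SD s exactly. This
#' is how printed "mean +/- SD" summaries are turned into sampling
#' distributions throughout the pipeline.
#'
#' @param mean,sd arithmetic mean (> 0) and standard deviation (> 0; a zero
#'   SD is accepted as the degenerate point-mass limit).
#' @return a lognormal `dist_spec`.
#' @examples
#' lognormal_from_moments(8.1, 19.4) # chronic botanicals consumption, g/day
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("sd must be nonnegative", call. = FALSE)
  s2 <- log1p((sd / mean)^2)
  structure(
    list(family = "lognormal",
         params = list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))),
    class = "dist_spec"
  )
}

#' Analytic mean and SD of a distribution specification
#'
#' @param spec a `dist_spec`.
#' @return named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  out <- switch(spec$family,
    normal = c(p$mean, p$sd),
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      c(m, m * sqrt(expm1(p$sdlog^2)))
    },
    exponential = c(1 / p$rate, 1 / p$rate),
    weibull = {
      m <- p$scale * gamma(1 + 1 / p$shape)
      v <- p$scale^2 * (gamma(1 + 2 / p$shape) - gamma(1 + 1 / p$shape)^2)
      c(m, sqrt(v))
    },
    pareto = {
      m <- if (p$alpha > 1) p$alpha * p$xm / (p$alpha - 1) else Inf
      v <- if (p$alpha > 2) {
        p$xm^2 * p$alpha / ((p$alpha - 1)^2 * (p$alpha - 2))
      } else Inf
      c(m, sqrt(v))
    },
    truncated_normal = {
      a <- (p$lower - p$mean) / p$sd
      b <- (p$upper - p$mean) / p$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      dm <- (stats::dnorm(a) - stats::dnorm(b)) / z
      m <- p$mean + p$sd * dm
      v <- p$sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - dm^2)
      c(m, sqrt(v))
    }
  )
  stats::setNames(out, c("mean", "sd"))
}

#' Seeded sampling from a distribution specification
#'
#' Draws are reproducible given `(spec, n, seed)`. Truncated-normal sampling
#' uses the inverse-CDF on the truncated interval (exact, no rejection).
#'
#' @param spec a `dist_spec`.
#' @param n number of draws.
#' @param seed integer seed for this stream.
#' @return numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  p <- spec$params
  withr::with_seed(seed, switch(spec$family,
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    exponential = stats::rexp(n, p$rate),
    weibull = stats::rweibull(n, p$shape, p$scale),
    pareto = p$xm / stats::runif(n)^(1 / p$alpha),
    truncated_normal = {
      pa <- stats::pnorm(p$lower, p$mean, p$sd)
      pb <- stats::pnorm(p$upper, p$mean, p$sd)
      u <- stats::runif(n, pa, pb)
      stats::qnorm(u, p$mean, p$sd)
    }
  ))
}

#' Closed-form CDF of a distribution specification
#'
#' @param spec a `dist_spec`.
#' @param x numeric vector of evaluation points.
#' @return `P(X <= x)`.
#' @export
dist_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    normal = stats::pnorm(x, p$mean, p$sd),
    lognormal = stats::plnorm(x, p$meanlog, p$sdlog),
    exponential = stats::pexp(x, p$rate),
    weibull = stats::pweibull(x, p$shape, p$scale),
    pareto = ifelse(x < p$xm, 0, 1 - (p$xm / x)^p$alpha),
    truncated_normal = {
      pa <- stats::pnorm(p$lower, p$mean, p$sd)
      pb <- stats::pnorm(p$upper, p$mean, p$sd)
      pmin(1, pmax(0, (stats::pnorm(x, p$mean, p$sd) - pa) / (pb - pa)))
    }
  )
}

#' @rdname dist_cdf
#' @param q probabilities.
#' @return `dist_quantile`: the quantile function evaluated at `q`.
#' @export
dist_quantile <- function(spec, q) {
  stopifnot(inherits(spec, "dist_spec"), all(q >= 0 & q <= 1))
  p <- spec$params
  switch(spec$family,
    normal = stats::qnorm(q, p$mean, p$sd),
    lognormal = stats::qlnorm(q, p$meanlog, p$sdlog),
    exponential = stats::qexp(q, p$rate),
    weibull = stats::qweibull(q, p$shape, p$scale),
    pareto = p$xm / (1 - q)^(1 / p$alpha),
    truncated_normal = {
      pa <- stats::pnorm(p$lower, p$mean, p$sd)
      pb <- stats::pnorm(p$upper, p$mean, p$sd)
      stats::qnorm(pa + q * (pb - pa), p$mean, p$sd)
    }
  )
}

#' Maximum-likelihood fit of one candidate family
#'
#' Families with analytic maximum-likelihood estimators are fitted in closed
#' form: normal (`mean(x)`, ML-denominator SD), lognormal (moments of the
#' log data), exponential (`rate = 1/mean(x)`) and the classic Pareto
#' (`xm = min(data)`, `alpha = n / sum(log(data/xm))`). The Weibull, which
#' has no closed form, is delegated to \code{fitdistrplus::fitdist}.
#'
#' @param data positive numeric vector, `length >= 3` (strict positivity is
#'   required for the positive-support families).
#' @param family candidate family tag (truncated_normal is not a candidate
#'   for concentration fitting).
#' @return a `fit_result`: list with `spec`, `loglik`, `aic`, `n`,
#'   `converged`; `delta_aic` is filled in by [select_by_aic()].
#' @export
fit_mle <- function(data, family) {
  family <- match.arg(family, setdiff(.dist_families, "truncated_normal"))
  data <- as.numeric(data)
  if (length(data) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(data))) stop("non-finite observations", call. = FALSE)
  positive_support <- family %in% c("lognormal", "exponential", "weibull", "pareto")
  if (positive_support && any(data <= 0)) {
    stop("family '", family, "' requires strictly positive data", call. = FALSE)
  }
  n <- length(data)
  res <- tryCatch(switch(family,
    pareto = {
      xm <- min(data)
      alpha <- n / sum(log(data / xm))
      ll <- n * log(alpha) + n * alpha * log(xm) - (alpha + 1) * sum(log(data))
      list(spec = dist_spec("pareto", xm = xm, alpha = alpha), loglik = ll)
    },
    exponential = {
      rate <- 1 / mean(data)
      list(spec = dist_spec("exponential", rate = rate),
           loglik = n * log(rate) - rate * sum(data))
    },
    normal = {
      mu <- mean(data)
      sigma <- sqrt(mean((data - mu)^2))
      spec <- dist_spec("normal", mean = mu, sd = sigma)
      list(spec = spec, loglik = sum(stats::dnorm(data, mu, sigma, log = TRUE)))
    },
    lognormal = {
      lx <- log(data)
      mu <- mean(lx)
      sigma <- sqrt(mean((lx - mu)^2))
      spec <- dist_spec("lognormal", meanlog = mu, sdlog = sigma)
      list(spec = spec, loglik = sum(stats::dlnorm(data, mu, sigma, log = TRUE)))
    },
    weibull = {
      fd <- fitdistrplus::fitdist(data, "weibull", method = "mle")
      est <- as.list(fd$estimate)
      list(spec = dist_spec("weibull", shape = est$shape, scale = est$scale),
           loglik = fd$loglik)
    }
  ), error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(list(family = family, spec = NULL, loglik = NA_real_,
                          aic = NA_real_, delta_aic = NA_real_, n = n,
                          converged = FALSE, message = conditionMessage(res)),
                     class = "fit_result"))
  }
  k <- unname(.dist_npar[family])
  structure(list(family = family, spec = res$spec, loglik = res$loglik,
                 aic = 2 * k - 2 * res$loglik, delta_aic = NA_real_, n = n,
                 converged = TRUE, message = NULL),
            class = "fit_result")
}

#' AIC model selection over candidate fits
#'
#' Ranks candidate fits of the same data by AIC and annotates each with its
#' delta-AIC evidence band: `"minimal (<3)"`, `"moderate (3-10)"`,
#' `"strong (>10)"` evidence against the candidate relative to the best.
#' Ties (identical AIC) break toward fewer parameters, then alphabetical
#' family order, so the winner is deterministic.
#'
#' @param fits list of `fit_result` objects from [fit_mle()] on identical data.
#' @return list with `winner` (a `fit_result`, `delta_aic = 0`) and `table`
#'   (ranked data.frame: family, n_par, loglik, aic, delta_aic, band,
#'   converged).
#' @export
select_by_aic <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) == 0) stop("all candidate fits failed", call. = FALSE)
  if (any(!ok)) {
    warning("excluding failed candidate(s): ",
            paste(vapply(fits[!ok], `[[`, "", "family"), collapse = ", "),
            call. = FALSE)
  }
  fits <- fits[ok]
  fam <- vapply(fits, `[[`, "", "family")
  aic <- vapply(fits, `[[`, 0, "aic")
  k <- unname(.dist_npar[fam])
  ord <- order(aic, k, fam)
  fits <- fits[ord]
  aic <- aic[ord]
  delta <- aic - aic[1]
  band <- cut(delta, c(-Inf, 3, 10, Inf),
              labels = c("minimal (<3)", "moderate (3-10)", "strong (>10)"),
              right = FALSE)
  for (i in seq_along(fits)) fits[[i]]$delta_aic <- delta[i]
  tab <- data.frame(
    family = vapply(fits, `[[`, "", "family"),
    n_par = unname(.dist_npar[vapply(fits, `[[`, "", "family")]),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = aic,
    delta_aic = delta,
    band = as.character(band),
    stringsAsFactors = FALSE
  )
  list(winner = fits[[1]], table = tab)
}

#' Fit all standard candidate families and select by AIC
#'
#' @param data positive numeric vector.
#' @param families candidate set (default: the five standard families).
#' @return as [select_by_aic()].
#' @export
fit_candidates <- function(data,
                           families = c("normal", "lognormal", "exponential",
                                        "weibull", "pareto")) {
  select_by_aic(lapply(families, function(f) fit_mle(data, f)))
}
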