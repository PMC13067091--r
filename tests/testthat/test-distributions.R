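test_that("lognormal moment matching inverts the analytic moments exactly", {
  cases <- list(c(8.1, 19.4), c(0.160, 0.081), c(3026, 18000), c(1, 1e-6),
                c(0.11, 0.27), c(16876, 31000))
  for (cs in cases) {
    spec <- lognormal_from_moments(cs[1], cs[2])
    m <- dist_moments(spec)
    expect_equal(unname(m["mean"]), cs[1], tolerance = 1e-12)
    expect_equal(unname(m["sd"]), cs[2], tolerance = 1e-9)
  }
  # frozen closed-form values for the chronic consumption pattern
  spec <- lognormal_from_moments(8.1, 19.4)
  expect_equal(spec$params$meanlog, 1.1381071, tolerance = 1e-6)
  expect_equal(spec$params$sdlog, 1.3811278, tolerance = 1e-6)
  expect_equal(exp(spec$params$meanlog), 3.121, tolerance = 1e-3)
  # degenerate limit: sd -> 0 collapses to a point mass at the mean
  tiny <- lognormal_from_moments(1, 1e-9)
  expect_equal(tiny$params$meanlog, 0, tolerance = 1e-12)
  expect_equal(tiny$params$sdlog, 0, tolerance = 1e-6)
  expect_error(lognormal_from_moments(-1, 1), "positive")
})

test_that("sampled moments of a moment-matched lognormal reproduce the inputs", {
  spec <- lognormal_from_moments(8.1, 19.4)
  x <- dist_sample(spec, 1e6, seed = 7)
  expect_equal(mean(x), 8.1, tolerance = 0.02)
  expect_equal(sd(x), 19.4, tolerance = 0.05)
})

test_that("closed-form MLEs are recovered", {
  # exponential likelihood by hand: data {1,2,4,8,16}
  fit <- fit_mle(c(1, 2, 4, 8, 16), "exponential")
  expect_equal(fit$spec$params$rate, 5 / 31, tolerance = 1e-5)
  expect_equal(fit$loglik, 5 * log(5 / 31) - 5, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik, tolerance = 1e-8)
  # k identical observations: rate = 1/c
  fit2 <- fit_mle(rep(3.5, 10), "exponential")
  expect_equal(fit2$spec$params$rate, 1 / 3.5, tolerance = 1e-5)
  # pareto analytic MLE on a hand-checkable set
  x <- c(1, 2, 4)
  fitp <- fit_mle(x, "pareto")
  expect_equal(fitp$spec$params$xm, 1)
  expect_equal(fitp$spec$params$alpha, 3 / (log(2) + log(4)), tolerance = 1e-10)
  expect_error(fit_mle(c(-1, 2, 3), "lognormal"), "positive")
  expect_error(fit_mle(c(1, 2), "normal"), "at least 3")
})

test_that("lognormal MLE matches the independent log-moment closed form", {
  x <- dist_sample(dist_spec("lognormal", meanlog = 0, sdlog = 1), 2000, seed = 11)
  fit <- fit_mle(x, "lognormal")
  lx <- log(x)
  mu_hat <- mean(lx)
  sd_hat <- sqrt(mean((lx - mu_hat)^2)) # ML denominator n
  expect_equal(fit$spec$params$meanlog, mu_hat, tolerance = 1e-4)
  expect_equal(fit$spec$params$sdlog, sd_hat, tolerance = 1e-3)
  # standard MLE sampling error band around the truth
  expect_lt(abs(fit$spec$params$meanlog - 0), 3 * 1 / sqrt(2000))
})

test_that("AIC selection recovers the generating family and breaks ties deterministically", {
  wins_ln <- 0
  wins_exp <- 0
  for (s in 1:20) {
    x <- dist_sample(dist_spec("lognormal", meanlog = 6.5, sdlog = 1.5), 2000, seed = s)
    if (fit_candidates(x)$winner$family == "lognormal") wins_ln <- wins_ln + 1
    # recovery is only well-posed against separated families: the Weibull
    # nests the exponential exactly, so it is excluded from this check
    y <- dist_sample(dist_spec("exponential", rate = 0.2), 2000, seed = 100 + s)
    sel <- fit_candidates(y, families = c("normal", "lognormal", "exponential", "pareto"))
    if (sel$winner$family == "exponential") wins_exp <- wins_exp + 1
  }
  expect_gte(wins_ln, 18)
  expect_gte(wins_exp, 18)

  sel <- fit_candidates(dist_sample(dist_spec("lognormal", meanlog = 6.5, sdlog = 1.5),
                                    2000, seed = 1))
  expect_equal(sel$winner$delta_aic, 0)
  expect_equal(sum(sel$table$delta_aic == 0), 1)
  expect_true(all(diff(sel$table$aic) >= 0))
  expect_true(all(sel$table$band %in%
                    c("minimal (<3)", "moderate (3-10)", "strong (>10)")))

  # identical AIC: fewer parameters win
  f1 <- structure(list(family = "exponential", spec = NULL, loglik = -10,
                       aic = 22, delta_aic = NA, n = 5, converged = TRUE),
                  class = "fit_result")
  f2 <- structure(list(family = "weibull", spec = NULL, loglik = -9,
                       aic = 22, delta_aic = NA, n = 5, converged = TRUE),
                  class = "fit_result")
  expect_equal(select_by_aic(list(f2, f1))$winner$family, "exponential")
})

test_that("sampling is seed-deterministic and matches the closed-form CDF", {
  specs <- list(
    dist_spec("lognormal", meanlog = 0, sdlog = 1),
    dist_spec("exponential", rate = 0.5),
    dist_spec("weibull", shape = 1.5, scale = 2),
    dist_spec("pareto", xm = 1, alpha = 2.5),
    dist_spec("normal", mean = 10, sd = 2),
    dist_spec("truncated_normal", mean = 182.5, sd = 70, lower = 1, upper = 365)
  )
  for (spec in specs) {
    a <- dist_sample(spec, 1000, seed = 3)
    b <- dist_sample(spec, 1000, seed = 3)
    expect_identical(a, b)
    x <- dist_sample(spec, 1e5, seed = 5)
    expect_lt(ks_distance(x, spec), 0.01)
  }
})

test_that("truncated-normal draws respect bounds and symmetric truncation keeps the mean", {
  spec <- dist_spec("truncated_normal", mean = 182.5, sd = 70, lower = 1, upper = 365)
  x <- dist_sample(spec, 1e5, seed = 2)
  expect_true(all(x >= 1 & x <= 365))
  expect_lt(abs(mean(x) - 182.5), 1)
  # truncation at [1, 365] is very slightly asymmetric around 182.5
  m <- dist_moments(spec)
  expect_lt(abs(unname(m["mean"]) - 182.5), 0.1)
})

test_that("closed-form CDF and quantile functions are mutually consistent", {
  spec <- lognormal_from_moments(0.160, 0.081)
  # median of a lognormal is exp(meanlog)
  expect_equal(dist_cdf(spec, exp(spec$params$meanlog)), 0.5)
  # analytic exceedance used as the Monte Carlo oracle downstream
  expect_equal(1 - dist_cdf(spec, 0.15), 0.4587, tolerance = 1e-3)
  expect_equal(dist_quantile(spec, 0.5), 0.1427, tolerance = 1e-3)
  e <- dist_spec("exponential", rate = 0.7)
  expect_equal(dist_cdf(e, log(2) / 0.7), 0.5)
  for (spec2 in list(spec, e, dist_spec("pareto", xm = 2, alpha = 3))) {
    q <- c(0.05, 0.25, 0.5, 0.9, 0.99)
    expect_equal(dist_cdf(spec2, dist_quantile(spec2, q)), q, tolerance = 1e-10)
  }
})

test_that("median of a lognormal sample is close to its analytic median", {
  x <- dist_sample(dist_spec("lognormal", meanlog = 0, sdlog = 1), 1e5, seed = 9)
  expect_equal(median(x), 1, tolerance = 0.02)
})
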