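test_that("baseline simulation reproduces the published intake summaries", {
  p <- simulate_baseline(test_reg, "P", 1e5, seed = 4)
  expect_equal(mean(p$values), 1269, tolerance = 0.01)
  expect_equal(p$units, "mg/day")
  pb <- simulate_baseline(test_reg, "Pb", 1e5, seed = 4)
  expect_equal(median(pb$values), 0.14275, tolerance = 0.02) # analytic lognormal median
  expect_equal(pb$units, "ug/kg bw/day")
  expect_error(simulate_baseline(test_reg, "Hg"), "unknown element")
})

test_that("botanicals intake is the product of independent lognormal factors", {
  # for independent lognormals the median of the product is the product of
  # the analytic medians -- an exact oracle for the intake equations
  cons_total <- lognormal_from_moments(8.1, 19.4)
  cons_bw <- lognormal_from_moments(0.11, 0.27)
  for (el in c("K", "P", "As", "Pb", "Ni")) {
    d <- simulate_botanicals_edi(test_reg, el, 1e5, seed = 6)
    spec <- get_concentration_dist(test_reg, el)
    cons <- if (get_element(test_reg, el)$class == "essential") cons_total else cons_bw
    expected <- exp(spec$params$meanlog) * exp(cons$params$meanlog) / 1000
    expect_equal(median(d$values), expected, tolerance = 0.03, label = el)
  }
  # published spot value: As botanicals-only median ~0.021 ug/kg bw/day
  as_d <- simulate_botanicals_edi(test_reg, "As", 1e5, seed = 6)
  expect_equal(median(as_d$values), 0.0208, tolerance = 0.05)
  expect_equal(as_d$units, "ug/kg bw/day")
  # streams are retained for sensitivity analysis, paired by iteration
  expect_equal(as_d$streams$concentration * as_d$streams$consumption / 1000,
               as_d$values, tolerance = 1e-12)
})

test_that("all botanicals-only intakes are right-skewed (mean above median)", {
  for (el in test_reg$elements$symbol) {
    d <- simulate_botanicals_edi(test_reg, el, 2e4, seed = 8)
    expect_gt(mean(d$values), median(d$values))
  }
})

test_that("combining scenarios is additive, dominating and share-consistent", {
  base <- simulate_baseline(test_reg, "Ca", 2e4, seed = 9)
  bot <- simulate_botanicals_edi(test_reg, "Ca", 2e4, seed = 9)
  comb <- combine_exposure(base, bot)
  expect_equal(comb$values, base$values + bot$values)
  expect_equal(mean(comb$values), mean(base$values) + mean(bot$values))
  expect_true(all(comb$values > base$values))
  share <- comb$streams$botanical_share
  expect_true(all(share > 0 & share < 1))
  expect_equal(share, bot$values / comb$values)
  other <- simulate_baseline(test_reg, "K", 2e4, seed = 9)
  expect_error(combine_exposure(other, bot), "element mismatch")
  short <- simulate_botanicals_edi(test_reg, "Ca", 100, seed = 9)
  expect_error(combine_exposure(base, short), "n_iter mismatch")
})

test_that("combined Ca reproduces the published total-intake median", {
  base <- simulate_baseline(test_reg, "Ca", 1e5, seed = 10)
  bot <- simulate_botanicals_edi(test_reg, "Ca", 1e5, seed = 10)
  comb <- combine_exposure(base, bot)
  expect_equal(median(comb$values), 876, tolerance = 0.05)
})

test_that("weekly conversion multiplies by 7 and lands in the TWI basis", {
  # constant-arithmetic oracle: 58.2 ug/kg bw/day -> 0.4074 mg/kg bw/week
  al <- simulate_baseline(test_reg, "Al", 1000, seed = 11)
  wk <- weekly_from_daily(al)
  expect_equal(wk$basis, "weekly")
  expect_equal(wk$units, "mg/kg bw/week")
  expect_equal(wk$values, al$values * 7 / 1000)
  expect_equal(wk$n_iter, al$n_iter)
  expect_error(weekly_from_daily(wk), "not on a daily basis")
  expect_equal(convert_units(58.2, "ug/kg bw/day", "mg/kg bw/week"), 0.4074)
  # essentials stay in mg, switching to a per-week basis
  kd <- simulate_baseline(test_reg, "K", 100, seed = 11)
  kw <- weekly_from_daily(kd)
  expect_equal(kw$units, "mg/week")
  expect_equal(kw$values, kd$values * 7)
  # published spot value: Al botanicals weekly median ~0.006 mg/kg bw/week
  alb <- weekly_from_daily(simulate_botanicals_edi(test_reg, "Al", 1e5, seed = 11))
  expect_equal(median(alb$values), 0.006, tolerance = 0.15)
})

test_that("acute Ni exposure follows the per-event equation", {
  ac <- simulate_acute(test_reg, "Ni", 1e5, seed = 12)
  expect_equal(ac$basis, "per-event")
  expect_equal(ac$units, "ug/kg bw/event")
  # product of analytic medians: 760 ug/kg x 0.0743 g/kg bw / 1000
  expect_equal(median(ac$values), 0.0565, tolerance = 0.05)
  expect_identical(ac$values, simulate_acute(test_reg, "Ni", 1e5, seed = 12)$values)
  expect_error(simulate_acute(test_reg, "Pb"), "no acute consumption reference")
  expect_error(simulate_acute(test_reg, "K"), "toxic elements only")
})
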