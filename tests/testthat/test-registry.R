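test_that("the bundled registry is complete and canonicalized", {
  reg <- test_reg
  expect_s3_class(reg, "rba_registry")
  expect_setequal(reg$elements$symbol,
                  c("Ca", "K", "P", "Mg", "Fe", "Zn", "Al", "Ni", "As", "Pb"))
  expect_equal(sum(reg$elements$class == "essential"), 6)
  expect_equal(sum(reg$elements$class == "toxic"), 4)
  expect_gte(nrow(reg$references), 14)
  expect_equal(nrow(reg$consumption), 3)
  expect_length(reg$products, 25)
  # concentration units: mg/kg for essentials and Al, ug/kg for Ni, As, Pb
  cu <- setNames(reg$elements$concentration_units, reg$elements$symbol)
  expect_true(all(cu[c("Ca", "K", "P", "Mg", "Fe", "Zn", "Al")] == "mg/kg"))
  expect_true(all(cu[c("Ni", "As", "Pb")] == "ug/kg"))
  # percentile ordering holds wherever percentiles are present
  cc <- reg$concentrations
  expect_true(all(cc$p5 <= cc$median & cc$median <= cc$p95))
})

test_that("registry lookups return the published anchors in canonical units", {
  expect_equal(get_reference(test_reg, "As", "BMDL", "skin cancer")$value, 0.06)
  expect_equal(get_reference(test_reg, "Pb", "BMDL", "nephrotoxicity")$value, 0.63)
  expect_equal(get_reference(test_reg, "Pb", "BMDL", "cardiovascular effects")$value, 1.5)
  expect_equal(get_reference(test_reg, "Ni", "LOAEL")$units, "ug/kg bw/event")
  expect_equal(get_reference(test_reg, "Al", "TWI")$units, "mg/kg bw/week")
  expect_equal(get_reference(test_reg, "Zn", "RfD")$value, 0.30)
  # the two Pb BMDLs force an endpoint disambiguation
  expect_error(get_reference(test_reg, "Pb", "BMDL"), "ambiguous")
  expect_error(get_reference(test_reg, "Hg", "TDI"), "no health reference")
  expect_equal(get_consumption(test_reg, "chronic_total_g_per_day")$mean, 8.1)
  expect_equal(get_consumption(test_reg, "chronic_g_per_kgbw_day")$sd, 0.27)
  expect_equal(get_consumption(test_reg, "acute_g_per_kgbw")$mean, 0.17)
})

test_that("unit conversion handles the intake dialects and rejects dimension mixes", {
  expect_equal(convert_units(1, "mg/kg bw/week", "ug/kg bw/week"), 1000)
  expect_equal(convert_units(0.0003, "mg/kg bw/day", "ug/kg bw/day"), 0.3)
  expect_equal(convert_units(58.2, "ug/kg bw/day", "mg/kg bw/week"), 0.4074)
  expect_equal(convert_units(5, "g/day", "mg/day"), 5000)
  expect_error(convert_units(1, "mg/day", "mg/kg bw/day"), "incompatible")
  expect_error(convert_units(1, "mg/kg", "mg/day"), "incompatible")
  expect_error(convert_units(1, "ug/kg bw/event", "ug/kg bw/day"), "incompatible")
  expect_error(convert_units(1, "stone/day", "mg/day"), "unrecognised")
})

test_that("baseline mean intakes reproduce the published percentages of the guidance values", {
  # this is the unit-canonicalization oracle: any mg/ug slip breaks these
  al <- get_baseline_moments(test_reg, "Al")
  twi <- get_reference(test_reg, "Al", "TWI")
  pct_al <- 100 * convert_units(al$mean, al$units, twi$units) /
    twi$value
  expect_equal(round(pct_al), 41)
  ni <- get_baseline_moments(test_reg, "Ni")
  tdi <- get_reference(test_reg, "Ni", "TDI")
  expect_equal(round(100 * ni$mean / tdi$value), 12)
  p <- get_baseline_moments(test_reg, "P")
  ai <- get_reference(test_reg, "P", "AI")
  expect_equal(round(100 * p$mean / ai$value), 231)
})

test_that("an incomplete or corrupt config fails loudly, naming the entry", {
  cfg <- yaml::read_yaml(default_registry_config())
  drop_pb <- cfg
  keep <- !vapply(drop_pb$health_references, function(r) {
    r$element == "Pb" && r$kind == "BMDL" && r$endpoint == "nephrotoxicity"
  }, logical(1))
  drop_pb$health_references <- drop_pb$health_references[keep]
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(drop_pb, f)
  expect_error(load_registry(f), "Pb, BMDL, nephrotoxicity")

  dup <- cfg
  dup$health_references <- c(dup$health_references, dup$health_references[14])
  yaml::write_yaml(dup, f)
  expect_error(load_registry(f), "duplicate")

  noel <- cfg
  noel$elements$Pb <- NULL
  noel$concentrations$Pb <- NULL
  noel$baseline_intake$Pb <- NULL
  yaml::write_yaml(noel, f)
  expect_error(load_registry(f), "missing element")

  expect_error(load_registry("/nonexistent/registry.yaml"), "not found")
})

test_that("the registry round-trips through serialization unchanged", {
  d <- withr::local_tempdir()
  jf <- file.path(d, "registry.json")
  dump_registry(test_reg, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$concentrations$mean, test_reg$concentrations$mean)
  expect_equal(back$baseline$sd, test_reg$baseline$sd)
  expect_equal(back$references$value, test_reg$references$value)
  expect_equal(back$products, test_reg$products)
  files <- dump_registry(test_reg, d)
  tab <- read.csv(file.path(d, "registry_baseline.csv"))
  expect_equal(tab$mean, test_reg$baseline$mean)
})
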