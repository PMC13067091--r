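# shared fixtures: the bundled registry and a shortcut for constant draws
test_reg <- load_registry()

constant_draws <- function(value, n = 100, element = "Ni", units = "ug/kg bw/day",
                           scenario = "botanicals", basis = "daily") {
  botanrisk:::new_exposure_draws(element, scenario, basis, units,
                                 rep(value, n), seed = 0)
}

# Kolmogorov distance between an empirical sample and a closed-form CDF
ks_distance <- function(x, spec) {
  x <- sort(x)
  n <- length(x)
  theo <- dist_cdf(spec, x)
  max(pmax(abs(seq_len(n) / n - theo), abs((seq_len(n) - 1) / n - theo)))
}
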