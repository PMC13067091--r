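# botanrisk

Probabilistic risk–benefit assessment of essential and potentially toxic
elements ingested through chronic consumption of botanical extracts, in the
context of the adult Italian diet.

Commercial botanical extracts carry both nutritionally valuable minerals
(Ca, K, P, Mg, Fe, Zn) and toxicologically relevant elements (Al, As, Ni,
Pb). `botanrisk` is for food-safety scientists and exposure modellers who
want to quantify, with full uncertainty propagation, how much such products
add to baseline dietary intake — on the benefit side as percentage
contributions to dietary reference values, and on the risk side as
percentages of tolerable intakes, margins of exposure, and the cumulative
non-carcinogenic hazard of the mixture.

## The model in brief

Every input is a published summary statistic (mean ± SD), turned into a
sampling distribution and propagated by seeded Monte Carlo (100 000
iterations by default):

* **Exposure.** Per iteration, intake from botanicals is
  `EDI = C × R / 1000` with concentration `C` drawn from the element's
  fitted family (lognormal for As, Ca, K, Mg, Ni, P, Pb; exponential for
  Fe, Zn, Al) and consumption `R` lognormal (8.1 ± 19.4 g/day total for
  essentials; 0.11 ± 0.27 g/kg bw/day for toxic elements). Baseline diet
  intake is lognormal from national-survey moments; the combined scenario
  is the iteration-wise sum. Lognormals are moment-matched exactly:
  `σ² = ln(1 + (s/m)²)`, `µ = ln m − σ²/2`.
* **Benefit.** `%DRV = 100·EDI/DRV` against EFSA adequate intakes /
  population reference intakes, with exact per-iteration additivity across
  diet components.
* **Risk.** `%TDI`/`%TWI` for Ni and Al (Al on a weekly basis),
  `MOE = BMDL/EDI` for As (skin cancer) and Pb (nephrotoxicity,
  cardiovascular), `MOE = LOAEL/exposure` for acute Ni in sensitized
  individuals, with threshold exceedance fractions (10, 30, 1).
* **Cumulative.** `THQ = (EDI/RfD) × Ef·Ed/At` with truncated-normal
  exposure frequency and duration and `At = 365·Ed` (so the factor is
  `Ef/365`), summed under dose addition into a hazard index over Al, As,
  Fe, Ni, Zn.
* **Sensitivity.** Spearman rank correlations between any output and the
  exact input streams that produced it.

A unit-aware registry vendors all published constants (element definitions,
Tables of intake moments, DRVs/HBGVs/reference points, US EPA RfDs) from a
bundled, reviewable YAML file, and a synthetic-data module can generate a
25-products × 10-elements concentration matrix with the assumed statistical
structure for end-to-end testing.

## Worked example

Combined (diet + botanicals) lead exposure and its margin of exposure for
nephrotoxicity:

```r
library(botanrisk)
reg <- load_registry()
print(reg)
#> <rba_registry> 10 elements, 21 health references, 3 consumption patterns, 25 products

pb_base <- simulate_baseline(reg, "Pb", n_iter = 1e5, seed = 42)
pb_bot  <- simulate_botanicals_edi(reg, "Pb", n_iter = 1e5, seed = 42)
pb_tot  <- combine_exposure(pb_base, pb_bot)
print(pb_tot)
#> <exposure_draws> Pb / combined (ug/kg bw/day, n_iter = 100000)
#>   mean 0.1741  sd 0.105  median 0.1534  P5-P95 0.07081-0.3421

moe <- margin_of_exposure(pb_tot, get_reference(reg, "Pb", "BMDL", "nephrotoxicity"))
print(moe)
#> <metric_draws> Pb / combined / moe vs BMDL (nephrotoxicity)
#>   mean 4.584  sd 2.31  median 4.106  P5-P95 1.842-8.897

round(100 * exceedance_fraction(moe, 10, "below"))
#> [1] 97
```

The median MOE of about 4 — far below the conventional concern threshold of
10, which 97% of iterations undercut — says that for a typical adult
consumer, combined dietary lead exposure sits within a factor ~4 of the
benchmark dose for kidney effects: baseline diet is the dominant driver and
botanicals worsen an already thin margin.

The cumulative assessment for botanicals alone:

```r
hd <- cumulative_risk(reg, scenario = "botanicals", n_iter = 1e5, seed = 42)
print(hd)
#> <hazard_decomposition> 5 elements
#>  component        mean          sd       median           p5         p95
#>         Al 0.001539544 0.007215285 0.0003289343 1.057055e-05 0.006139937
#>         As 0.515149552 7.083329765 0.0317067470 5.868180e-04 1.611914861
#>         Fe 0.004309968 0.014629533 0.0009213281 2.933367e-05 0.017645578
#>         Ni 0.006618169 0.038985670 0.0007303106 2.155735e-05 0.023305153
#>         Zn 0.001652040 0.006133391 0.0003500239 1.119622e-05 0.006730969
#>         HI 0.529269272 7.083498761 0.0470750496 3.832977e-03 1.630988585
#> mean-HI shares (%): Al 0.3, As 97.3, Fe 0.8, Ni 1.3, Zn 0.3
```

Arsenic contributes ~97% of the mean hazard index; the median consumer is
comfortable (HI ≈ 0.05) but the upper tail (P95 ≈ 1.6) crosses the
HI = 1 line — the risk is concentrated in high-concentration products and
heavy consumers.

`run_full_study(reg, n_iter = 1e5, seed = 42)` executes every scenario,
metric, exceedance, cumulative and sensitivity computation in one call and
`write_bundle()` renders the result as CSVs plus a provenance-stamped JSON.
A thin command-line wrapper over the same functions ships in
`inst/cli/rba.R` (subcommands `run-all`, `registry`, `simulate`,
`cumulative`, `sensitivity`).

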