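---
title: "Probabilistic risk-benefit assessment of elements in botanical extracts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic risk-benefit assessment of elements in botanical extracts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Powdered botanical extracts are consumed chronically by a substantial share
of adults, and they carry both essential minerals (Ca, K, P, Mg, Fe, Zn) and
potentially toxic elements (Al, As, Ni, Pb). `botanrisk` implements a
probabilistic (Monte Carlo) risk-benefit assessment of this exposure for the
adult Italian diet: it asks how much botanical extracts add to baseline
mineral intake (the benefit side), whether that addition pushes toxic-element
exposure past health-based guidance values or erodes margins of exposure (the
risk side), and what the cumulative non-carcinogenic burden of the mixture
is.

All inputs are summary statistics: concentration summaries over 25 commercial
extracts, national survey intake summaries, consumer-only consumption
summaries, and the EFSA/US-EPA reference values. No raw measurement data are
required; the package's synthetic-data module can materialize a plausible
25 x 10 concentration matrix for end-to-end testing, and clearly labels it as
synthetic.

```{r, eval = FALSE}
library(botanrisk)
reg <- load_registry()
study <- run_full_study(reg, n_iter = 1e5, seed = 42)
```

## Exposure model

Three chronic scenarios are simulated for every element, each with 100 000
Monte Carlo iterations by default:

* **baseline** — intake from the total diet excluding botanicals, lognormal,
  moment-matched to the published mean ± SD;
* **botanicals** — intake from extracts alone. Per iteration, an independent
  concentration draw $C_i$ and consumption draw $R_i$ give
  $\mathrm{EDI}_i = C_i R_i / 1000$. Essential elements pair mg/kg
  concentrations with the total consumption pattern (8.1 ± 19.4 g/day),
  yielding mg/day; toxic elements pair µg/kg concentrations with the
  body-weight-normalized pattern (0.11 ± 0.27 g/kg bw/day), yielding
  µg/kg bw/day;
* **combined** — the iteration-wise sum of the two (defined only for
  elements with a baseline entry). The per-iteration botanical share
  $b_i/(a_i+b_i)$ is retained.

A fourth, **acute**, scenario exists for Ni only (the one element with a
per-event reference point): one concentration draw times one acute
consumption draw (0.17 ± 0.35 g/kg bw per event) / 1000.

Al is judged against a weekly guidance value, so its daily draws are
multiplied by 7 and re-expressed in mg/kg bw/week before comparison; the
metric layer refuses a daily/weekly basis mismatch outright.

### Distributional assumptions

Consumption and baseline intakes are lognormal — the standard choice for
right-skewed nutrition and consumption data when only a mean and SD are
available. The lognormal is parameterized by exact moment matching:
$\sigma^2 = \ln(1 + (s/m)^2)$, $\mu = \ln m - \sigma^2/2$, so the analytic
mean and SD equal the printed values to machine precision.

Concentrations across extracts follow the families selected by AIC on the
measured data: lognormal for As, Ca, K, Mg, Ni, P and Pb; exponential for
Fe, Zn and Al. (The published family lists contain an element label that can
only be read as Zn, since the two lists must partition the ten elements and
Ni already appears among the lognormals; the registry adopts that reading.)
Lognormal concentration models are moment-matched; exponential models use
rate $1/\text{mean}$, the exponential MLE given a mean. This is the one place
the package must deviate from the original computation: the original fits
were MLE on the raw 25-sample data, which are unpublished, so moment matching
on the printed summaries is the only faithful reconstruction available. For
moderately skewed elements the difference is negligible; for As — mean
3026, SD 18 000 µg/kg, log-scale SD ≈ 1.9 — quantities driven by the As tail
(the As target hazard quotient and the hazard-index mean/upper percentiles)
are the most parameterization-sensitive outputs and carry the widest
tolerances in the test suite.

The distribution toolkit also implements the five-family AIC fitting
workflow itself (`fit_mle()`, `select_by_aic()`), so the family-selection
step can be rerun on any future raw data: closed-form MLEs for the normal,
lognormal, exponential and classic Pareto ($x_m = \min x$,
$\hat\alpha = n / \sum \ln(x_i/x_m)$), `fitdistrplus` for the Weibull, AIC
$= 2k - 2\ell$, and delta-AIC evidence bands (minimal < 3, moderate 3–10,
strong > 10) with a parsimony-then-alphabetical tie-break so selection is
deterministic.

## Benefit and risk metrics

For essentials, the per-iteration percentage of the dietary reference value
is $100\,\mathrm{EDI}_i/\mathrm{DRV}$; the combined version is computed so
that the total percentage is *exactly* the sum of the two component
percentages. For Ni and Al the same quotient runs against the tolerable
daily/weekly intake. For As and Pb the margin of exposure is
$\mathrm{MOE}_i = \mathrm{BMDL}/\mathrm{EDI}_i$ (skin-cancer BMDL05 for As;
nephrotoxicity BMDL10 and cardiovascular BMDL01 for Pb), and for acute Ni
$\mathrm{MOE}_i = \mathrm{LOAEL}/E_i$ with the 4.3 µg/kg bw LOAEL for
systemic contact dermatitis in sensitized individuals.

Interpretation thresholds (MOE below 10 for BMDL-based concern, below 30
for Ni sensitization, below 1 for exposure exceeding the reference point)
are carried as data annotations, not hard-coded logic, and exceedance
fractions use strict inequality — the boundary is a measure-zero event under
continuous models.

Because MOE is a deterministic reciprocal of intake on the same draws,
empirical quantiles obey the duality $Q_p(\mathrm{MOE}) =
\mathrm{BMDL}/Q_{1-p}(\mathrm{EDI})$, and baseline-only exceedance fractions
have a closed lognormal form $1 - \Phi((\ln(\mathrm{BMDL}/c) - \mu)/\sigma)$;
both serve as exact oracles in the test suite.

## Cumulative risk

The non-carcinogenic mixture model covers Al, As, Fe, Ni and Zn — the
elements with US EPA chronic oral reference doses (RfDs); Pb has none and is
assessed by MOE only. Total measured As is treated as inorganic As, a
deliberately conservative reading given that most arsenic in botanicals is
inorganic. Per iteration,

$$\mathrm{THQ}_i = \frac{\mathrm{EDI}_i}{\mathrm{RfD}} \times
  \frac{Ef_i \, Ed_i}{At_i}, \qquad At_i = 365\,Ed_i,$$

with exposure frequency $Ef \sim$ truncated normal (mean 182.5 days/year,
SD 70, range 1–365) and duration $Ed \sim$ truncated normal (mean 23 years,
SD 10, range 1–46). $Ed$ cancels algebraically, leaving a factor
$Ef_i/365 \in (0,1]$; the package samples $Ed$ anyway for transparency and
asserts the cancellation by test. One exposure-factor stream is shared by
all elements within an iteration — dose addition presumes the same consumer
co-ingests them — and the factor applies in the combined scenario too, as
the quotient's definition prescribes. The hazard index is the iteration-wise
sum of THQs, with the decomposition of the mean HI into per-element shares.

In the cumulative model all five doses are computed on the per-bodyweight
basis (the body-weight-normalized consumption pattern for the botanical
part); Fe and Zn baseline intakes, published in mg/day, are divided by a
configurable adult body weight. No body weight is stated with the published
inputs; the package default is a 70 kg point value, the conventional adult
reference, exposed as the `bw` argument.

## Sensitivity analysis

`spearman_sensitivity()` correlates any output with the exact input streams
that produced it (paired iterations), using Spearman rank correlation —
Pearson correlation of midranks with average ranks under ties, which is what
`stats::cor(method = "spearman")` computes. It is invariant under monotone
transforms, and for a ratio of independent lognormals the closed form
$\rho = -(6/\pi)\arcsin(r/2)$ with
$r = \sigma_X/\sqrt{\sigma_X^2+\sigma_Y^2}$ provides an independent check of
both sign and magnitude. Sensitivity is reported for the botanicals-only
outputs, where the modeled inputs (concentration, consumption rate) are the
only sources of variability.

## Units and the registry

Every quantity carries a unit string from a small closed dialect
(`mg/day`, `ug/kg bw/day`, `mg/kg bw/week`, `g/kg bw/event`, ...);
conversions are powers of 1000 on the mass prefix and a factor 7 between
daily and weekly bases, and anything else is a dimension error. The
published tables are not unit-consistent as printed: the toxic-element
intake and guidance-value rows print "mg kg BW⁻¹" where only µg reproduces
the published percentages (58.2/day against a 1 mg/kg bw/week weekly limit
gives the published 41% only in µg; the acute Ni reference point is
elsewhere printed as 4.3 µg/kg bw). The registry therefore stores those
values in µg, and a load-time oracle — baseline mean over guidance value
must reproduce the published 41% (Al), 12% (Ni) and 231% (P) — guards the
canonicalization. Two further registry conventions: the Mg UL (250 mg/day)
applies to supplemental Mg only and is stored with a note, never as a
total-diet cap; the Zn PRI is the single published average over the four
phytate levels.

## Randomness and reproducibility

All randomness flows from one root seed. Each stream (element x scenario x
role) derives its own sub-seed from the root seed plus a string key, so
streams are mutually independent, individually reproducible, and the entire
`run_full_study()` bundle is bit-reproducible from one integer. Truncated
normals are sampled by inverse CDF on the truncated interval (exact, fully
vectorized, no rejection pathologies).

## What the synthetic generator does and does not emulate

`generate_concentrations()` draws each element column independently from its
fitted family at the published moments. It reproduces marginal
distributions, right skew (sample mean above median at n = 25 in essentially
every seed, for the heavy-tailed columns) and strictly positive support
(published 5th percentiles of 0 are rounding artifacts, not censored
zeros). It does **not** model inter-element correlation (no correlation
structure was published; columns are sampled independently and this is a
known limitation), per-product systematic differences (product labels are
cosmetic metadata), or values below analytical quantification limits.
Passing tests on synthetic tables therefore validate the pipeline's
arithmetic and statistical behaviour, not the field accuracy of any specific
extract.

## Numerical choices

* Percentiles: linear interpolation of order statistics
  (`stats::quantile`, type 7), stated so summaries are reproducible.
* Moment matching uses `log1p`/`expm1` to stay exact in the small-CV limit;
  an SD of zero degenerates cleanly to a point mass.
* AIC ties break to fewer parameters, then alphabetical family order.
* Exceedance fractions use strict inequality at cutpoints.
* Failed candidate fits are excluded from model selection with a warning
  rather than aborting it; selection errors only if every candidate fails.

## Problem sizes

The package defaults to the published design size of 100 000 iterations per
stream; the full acceptance workflow runs at that size. Unit and property
tests use 10^4–10^5 draws where a distributional statement is under test and
a few hundred where only algebra or structure is, which keeps the default
suite fast while leaving every statistical tolerance honest at its stated
iteration count.

## Known limitations

* Moment-matched lognormals stand in for MLE fits to unpublished raw data;
  heaviest-tail outputs (As THQ, HI mean and P95) inherit the discrepancy.
* One-dimensional Monte Carlo: variability and parameter uncertainty are
  propagated together, not separated into a 2D design.
* No bioavailability adjustment, no age/sex stratification, no
  per-product exposure, and no composite risk-benefit currency (DALY/QALY);
  the assessment deliberately stays at the tier of separate benefit and risk
  metrics.
* The combined acute scenario is intentionally undefined (no acute baseline
  consumption pattern exists), mirroring the study design.
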