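# botanrisk registry: elements, concentration summaries in botanical
# extracts, baseline dietary intake of Italian adults, botanical consumption
# patterns, and the benefit/risk anchors (DRVs, HBGVs, reference points,
# US EPA RfDs). Units use the package dialect: ug == micrograms; "kg bw" is
# per kilogram body weight; concentrations are per kg of dry extract.
#
# Tolerable-intake and reference-point values for the toxic elements are
# stored in micrograms per kg body weight (the only reading consistent with
# the published percentages they are paired with).

elements:
  Ca: {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  K:  {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  P:  {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  Mg: {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  Fe: {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  Zn: {class: essential, concentration_units: mg/kg, intake_units: mg/day}
  Al: {class: toxic, concentration_units: mg/kg, intake_units: ug/kg bw/day}
  Ni: {class: toxic, concentration_units: ug/kg, intake_units: ug/kg bw/day}
  As: {class: toxic, concentration_units: ug/kg, intake_units: ug/kg bw/day}
  Pb: {class: toxic, concentration_units: ug/kg, intake_units: ug/kg bw/day}

# Concentration summaries across the 25 extracts (per kg dry extract) and
# the best-fitting family used for probabilistic sampling.
concentrations:
  K:  {family: lognormal,   mean: 16876, sd: 31000, median: 8337, p5: 398, p95: 58406, units: mg/kg}
  P:  {family: lognormal,   mean: 1605,  sd: 2000,  median: 986,  p5: 76,  p95: 5009,  units: mg/kg}
  Ca: {family: lognormal,   mean: 1400,  sd: 2300,  median: 756,  p5: 42,  p95: 4857,  units: mg/kg}
  Mg: {family: lognormal,   mean: 878,   sd: 1300,  median: 506,  p5: 35,  p95: 2820,  units: mg/kg}
  Fe: {family: exponential, mean: 55,    sd: 55,    median: 38,   p5: 0,   p95: 165,   units: mg/kg}
  Zn: {family: exponential, mean: 9.0,   sd: 9.0,   median: 6.2,  p5: 0.0, p95: 26.9,  units: mg/kg}
  Al: {family: exponential, mean: 28,    sd: 28,    median: 20,   p5: 0,   p95: 85,    units: mg/kg}
  Ni: {family: lognormal,   mean: 2433,  sd: 7400,  median: 719,  p5: 13,  p95: 9478,  units: ug/kg}
  As: {family: lognormal,   mean: 3026,  sd: 18000, median: 649,  p5: 7,   p95: 11623, units: ug/kg}
  Pb: {family: lognormal,   mean: 128,   sd: 220,   median: 66,   p5: 3,   p95: 438,   units: ug/kg}

# Baseline dietary intake, adults (mean +/- SD), modelled lognormal.
baseline_intake:
  K:  {mean: 3026,  sd: 875,   units: mg/day}
  P:  {mean: 1269,  sd: 366,   units: mg/day}
  Mg: {mean: 279,   sd: 87,    units: mg/day}
  Ca: {mean: 914,   sd: 317,   units: mg/day}
  Fe: {mean: 8.7,   sd: 2.9,   units: mg/day}
  Zn: {mean: 10.7,  sd: 3.3,   units: mg/day}
  As: {mean: 0.081, sd: 0.030, units: ug/kg bw/day}
  Ni: {mean: 1.55,  sd: 0.72,  units: ug/kg bw/day}
  Al: {mean: 58.2,  sd: 25.0,  units: ug/kg bw/day}
  Pb: {mean: 0.160, sd: 0.081, units: ug/kg bw/day}

# Botanical-extract consumption by adult consumers (mean +/- SD), lognormal.
consumption:
  chronic_total_g_per_day:  {mean: 8.1,  sd: 19.4, units: g/day}
  chronic_g_per_kgbw_day:   {mean: 0.11, sd: 0.27, units: g/kg bw/day}
  acute_g_per_kgbw:         {mean: 0.17, sd: 0.35, units: g/kg bw/event}

# Benefit anchors (EFSA DRVs), risk anchors (EFSA HBGVs / reference points)
# and US EPA chronic oral reference doses for the cumulative assessment.
health_references:
  - {element: K,  kind: AI,    value: 3500, units: mg/day, endpoint: adequacy, basis: daily}
  - {element: P,  kind: AI,    value: 550,  units: mg/day, endpoint: adequacy, basis: daily}
  - {element: P,  kind: UL,    value: 3000, units: mg/day, endpoint: excess, basis: daily}
  - {element: Ca, kind: PRI,   value: 950,  units: mg/day, endpoint: adequacy, basis: daily}
  - {element: Ca, kind: UL,    value: 2500, units: mg/day, endpoint: excess, basis: daily}
  - {element: Mg, kind: AI,    value: 325,  units: mg/day, endpoint: adequacy, basis: daily}
  - {element: Mg, kind: UL,    value: 250,  units: mg/day, endpoint: excess, basis: daily,
     note: supplemental Mg only, not a total-diet cap}
  - {element: Fe, kind: PRI,   value: 11,   units: mg/day, endpoint: adequacy, basis: daily}
  - {element: Zn, kind: PRI,   value: 11.5, units: mg/day, endpoint: adequacy, basis: daily,
     note: arithmetic mean over the four phytate-level PRIs}
  - {element: Zn, kind: UL,    value: 25,   units: mg/day, endpoint: excess, basis: daily}
  - {element: Al, kind: TWI,   value: 1,    units: mg/kg bw/week, endpoint: neurotoxicity, basis: weekly}
  - {element: Ni, kind: TDI,   value: 13,   units: ug/kg bw/day, endpoint: reproductive and developmental toxicity, basis: daily}
  - {element: Ni, kind: LOAEL, value: 4.3,  units: ug/kg bw/event, endpoint: systemic contact dermatitis, basis: per-event}
  - {element: As, kind: BMDL,  value: 0.06, units: ug/kg bw/day, endpoint: skin cancer, basis: daily,
     note: BMDL05}
  - {element: Pb, kind: BMDL,  value: 1.5,  units: ug/kg bw/day, endpoint: cardiovascular effects, basis: daily,
     note: BMDL01}
  - {element: Pb, kind: BMDL,  value: 0.63, units: ug/kg bw/day, endpoint: nephrotoxicity, basis: daily,
     note: BMDL10}
  - {element: Al, kind: RfD,   value: 1.00,   units: mg/kg bw/day, endpoint: chronic non-carcinogenic, basis: daily}
  - {element: As, kind: RfD,   value: 0.0003, units: mg/kg bw/day, endpoint: chronic non-carcinogenic, basis: daily}
  - {element: Fe, kind: RfD,   value: 0.7,    units: mg/kg bw/day, endpoint: chronic non-carcinogenic, basis: daily}
  - {element: Ni, kind: RfD,   value: 0.02,   units: mg/kg bw/day, endpoint: chronic non-carcinogenic, basis: daily}
  - {element: Zn, kind: RfD,   value: 0.30,   units: mg/kg bw/day, endpoint: chronic non-carcinogenic, basis: daily}

# Commercial product labels for the synthetic concentration table (cosmetic
# row metadata only; per-product concentrations are not modelled).
products:
  - Gardenia extract
  - Garcinia Mangostana fruit rind extract
  - Sea Buckthorn extract
  - Hawthorn extract
  - Cayenne extract
  - Lingustrin lucidum extract
  - Black garlic extract
  - Java tea extract
  - Gymnema Sylvestre extract (75%)
  - Rosemary extract
  - Ginkgo Biloba extract
  - Green Tea Extract
  - Dandelion extract
  - Walnut extract
  - Grape Skin extract
  - Pomegranate extract
  - Cordyceps sinensis extract (4:1)
  - Reishi mushroom extract
  - Cordyceps extract (beta glucan)
  - Beetroot powder E2.6
  - Sarsaparilla extract
  - Skullcap extract
  - Nettle Root extract
  - Guarana extract (10% caffeine)
  - Red yeast rice extract
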