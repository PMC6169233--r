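---
title: "Methods: probabilistic cancer risk assessment for PAH mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic cancer risk assessment for PAH mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Polycyclic aromatic hydrocarbons (PAHs) occur in the environment as complex
mixtures, and many members of the class are carcinogenic. `pahrisk`
implements a chain of standard environmental-health computations for such a
mixture, anchored to a heavily PAH-contaminated estuarine sediment from a
former wood-treatment site:

1. **Mixture annotation** — which mixture components are on the EPA list of
   16 priority PAHs, and which carry a structure–activity carcinogenic
   concern ranking.
2. **Deterministic risk equations** — excess lifetime cancer risk for
   receptors in direct oral or dermal contact with the sediment.
3. **Monte Carlo uncertainty propagation** — distributions of that risk
   when exposure factors are uncertain.
4. **Reverse dosimetry** — back-calculation of population daily intake from
   urinary metabolite biomarkers, stratified by demographics.
5. **Impact characterization** — pooling compartment × route intake
   fractions and health effect factors for the mixture.

## Mixture annotation

A `mixture_profile` holds one row per compound: concentration (ng/mL),
measurement SD, EPA priority flag, and an *ordered* concern level

```
none < marginal < low < low-moderate < moderate < moderate-high < high
```

Two conventions matter and are deliberate:

* Blank concern cells map to `none`, not `marginal` — marginal/negligible
  rankings are not carried into results in the screening convention the
  packaged table follows.
* "Of carcinogenic concern" defaults to the threshold `low-moderate`. This
  is the only threshold under which the packaged 35-compound sediment
  profile yields its published headline count of eleven compounds of
  concern, and it is exposed as an argument rather than hard-coded.
* The zero-concentration row (3-Methylcholanthrene) is retained: presence
  in the measured profile is information even at 0 ng/mL.

The packaged profile lists 35 compounds. The mixture is described elsewhere
as having 36 components; the printed table carries 35 rows, and the package
ships exactly what is printed.

```{r}
mix <- paper_mixture()
count_priority(mix)
count_concern(mix)
```

## Deterministic risk equations

For a receptor group (adult/child trespasser, adult/child recreational
user) and route, exposure is

* oral: `CDI = CS · IR_S · FI · EF · ED · CF / (BW · AT)` (mg/kg-day)
* dermal: `DA_event = CS · CF · AF · ABSd`;
  `DAD = DA_event · EF · ED · EV · SA / (BW · AT)`

and risk is exposure times the summed hazard `Σ_c CSF_c · ADAF` over the
seven sediment contaminants of concern. Central parameter values are
packaged (`table1_distributions()`, `table1_scenario()`,
`cancer_slopes()`): total COC sediment concentration `CS = 0.283` mg/kg,
averaging time `AT = 25550` days (70 years, held fixed), conversion factor
`CF = 1e-6` kg/mg, and an age-dependent adjustment factor `ADAF` of 1 for
adults and 10 for children. The oral slope factors sum to 16.8703
(mg/kg-day)⁻¹ and the dermal ones to 57.775.

Two design points were genuinely open:

* **Shared-concentration convention.** The packaged configuration prints a
  *single* sediment concentration for the seven-COC total alongside seven
  per-compound slope factors. The default mode therefore drives the
  exposure term with that single `CS` and sums per-compound hazards over
  it. Whether one should instead apportion `CS` among compounds is
  unknowable from the printed configuration, so a per-compound mode
  (`cs_by_compound` in `compute_risk()`) is provided for general use.
* **`FI` and `EV`.** The oral equation contains a fraction-ingested term
  and the dermal equation an events/day term, but neither appears in the
  packaged parameter table. Both default to 1 — the conservative, standard
  choice in the underlying exposure guidance — and are configurable.

Validation is strict-positive by default; `validate = "relaxed"` admits
zeros so the analytic edge cases (linearity through the origin) can be
exercised.

## Monte Carlo propagation

The uncertainty statement for every randomized factor is "± 25% of the
mean". The sampling model is **uniform** on
`[mean − half_width, mean + half_width]`: a minimum and a maximum alone
determine no other distribution, so uniform is the honest choice. A
truncated-normal family (`sd = half_width/2`, truncated to the same
support) is available behind `family = "truncnorm"` but is off by default.
Factors are sampled independently — no correlation structure is asserted
anywhere in the source configuration.

Randomized sets follow the stated protocol exactly: oral `IR_S, EF, ED,
BW`; dermal `EF, ED, AF, SA, BW`. Everything else (`CS`, `CF`, `AT`,
`ADAF`, `FI`, `EV`, `ABSd`) stays fixed. The reference run is 10,000
iterations per group × route.

Summaries report mean, SD, extrema, median, 2.5/97.5 percentiles (linear
interpolation, R type 7), the normal-approximation 95% CI of the mean
(`mean ± 1.96·sd/√n`; a percentile bootstrap is available), and adjusted
Fisher–Pearson sample skewness. Seeds are recorded on the draw vector and
in all pipeline manifests; a fixed seed reproduces draws bit for bit
because factors are drawn in the configuration's row order.

One empirical note: a product of symmetric factors with a reciprocal
body-weight term is right-skewed, and the package reports the signed
skewness it computes rather than forcing agreement with any qualitative
description of the distributions' shape.

```{r}
cfg <- simulation_config("adult_trespasser", "oral",
                         n_iterations = 2000, seed = 1)
summarize_distribution(simulate_risk(cfg))[, c("mean", "sd", "skewness")]
```

## Reverse dosimetry

Daily intake of a parent PAH is back-calculated from the urinary
concentration of its metabolite:

```
intake (µg/kg-day) = conc_urine · urine_output · MW_parent /
                     (excretion_fraction · body_weight · MW_metabolite)
```

This is a deliberately simple steady-state ("back-of-the-envelope") model,
not a physiologically based pharmacokinetic one. Excretion fractions,
molecular weights, urine output (1.6 L/day) and body weight (80 kg) are
**configuration inputs with documented defaults** (`default_kinetics()`,
`population_constants()`): the defaults are literature-plausible values,
not measured ground truth, and absolute intake levels computed from them
should be read accordingly. Rankings across strata, by contrast, are
invariant to any positive rescaling of these constants, which is why the
module's emphasis is on `rank_strata()`.

Urinary concentrations are treated as unadjusted geometric means (the
population-biomonitoring reporting convention); replicate records within a
stratum are combined by geometric mean by default. One metabolite per
parent is the packaged configuration; parents with several measured
metabolites can be handled by summing metabolite-wise estimates
(`combine_metabolites = "sum"`).

## Impact characterization

Characterization records — intake fraction (kg intaken per kg emitted) and
effect factors (cancer cases/kg, DALY/kg) per (compound, compartment,
route) — are *inputs*: the multimedia fate model that produces them is out
of scope, and no third-party database is bundled. The module pools records
over a compound set, apportions a compartment's intake across exposure
routes (shares sum to 1; zero-intake compartments raise an explicit error
rather than emitting 0/0), and sums pooled health effects per compartment.
All operations are plain additive aggregations, so pooled results equal
sums of single-compound results to machine precision.

## Synthetic data

`synthesis_spec()` fixes the study conditions for the generators:

* **Mixtures** — log-uniform concentrations over three decades below the
  requested scale, priority flags and concern levels drawn from a frequency
  table mirroring the packaged sediment profile; `preset = "paper"` returns
  the packaged measured profile itself.
* **Biomarkers** — exact forward images of known ground-truth intakes
  (defaults 0.30/0.05/0.08/0.04 µg/kg-day for naphthalene, fluorene,
  phenanthrene, pyrene, naphthalene dominant as in population
  biomonitoring), multiplied by per-stratum factors (smokers 3×,
  secondhand-exposed 1.5×, non-Hispanic black participants 1.5× — the
  qualitative exposure gradients reported for these groups). Noise is
  multiplicative lognormal with median 1, parameterized by a coefficient of
  variation, so geometric means remain unbiased for the truth.
* **Characterization tables** — effect totals strictly halving along the
  compartment ordering fresh water > sea water > agricultural soil >
  natural soil, with fish-dominated route shares (60% fish, 15% drinking
  water, 12% produce, 8% meat/dairy, 5% inhalation) in every compartment.

What passing tests on these generators shows: the estimators invert the
forward models, orderings built into the truth are recovered, and every
pipeline stage composes deterministically under a seed. What they do not
show: agreement with real survey data — the generators emulate neither the
survey's sampling design (weights, clustering) nor seasonal or
within-person biomarker variability, and the characterization tables carry
made-up magnitudes with only the qualitative structure fixed.

## Problem sizes and numerical choices

The test suite runs groups at 2,000–10,000 Monte Carlo iterations and the
noisy round-trip recovery at 500 replicates per stratum — sizes at which
the suite completes in well under a minute while keeping Monte Carlo
standard errors far below the tolerances asserted. Percentiles use linear
interpolation; ties in rankings and top-k lists break alphabetically;
histogram bins are equal-width over `[min, max]` with a single-bin
degenerate case for constant input. Sub-seeds for multi-run procedures are
drawn by `sample.int` from the master seed so runs are independent but
reproducible.

## Known limitations

* Absolute reverse-dosimetry intakes inherit the uncertainty of the
  default kinetic constants; only ratios and rankings are robust.
* The risk engine covers direct oral and dermal sediment contact only — no
  inhalation route, no non-cancer hazard quotients, and no indirect dietary
  pathways (e.g. consumption of seafood from a contaminated site), which
  can dominate total site risk.
* The shared-concentration convention ties the headline risk numbers to
  the packaged seven-COC configuration; for other mixtures use the
  per-compound mode with compound-specific concentrations.
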