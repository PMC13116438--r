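---
title: "Methods: from peak areas to per-capita consumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peak areas to per-capita consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbequant)
```

# Scope

`wbequant` models the computational half of a targeted LC-MS/MS wastewater
surveillance workflow. Everything upstream of peak integration — solid
phase extraction, chromatography, ion-source physics, peak picking — is out
of scope; peak areas, heights and baseline noise estimates are inputs. The
pipeline stages are: panel resolution, isotope-dilution calibration,
signal-to-noise sensitivity limits, censored quantitation with QC gating,
spike-recovery evaluation, and flow/population back-calculation.

# The quantitation model and its assumptions

Isotope dilution assumes the labelled internal standard co-elutes with its
native analyte and experiences the same per-injection multiplicative
effects (injection volume, ionization suppression or enhancement). Under
that assumption the response ratio

$$y_{is} = \frac{A_{is}}{A_{\mathrm{IS}(i),s}}$$

is free of common-mode matrix effects, and a single line $y = a c + b$ per
compound maps ratios to extract concentrations. The assumption is weakest
for natives assigned a *surrogate* standard (a labelled compound of the
same class rather than the exact analog); the packaged panel marks every
assignment explicitly, as data, so users can tighten it when exact analogs
become available.

## Calibration weighting and acceptance

The default design covers 0.001–200 ng/mL in 22 geometrically spaced
levels — over five orders of magnitude. An unweighted least-squares fit on
such a range is dominated by the top calibrants: its intercept error alone
can exceed the entire signal at the bottom of the range. The default
weighting is therefore $1/x$, with `none` and $1/x^2$ selectable. The test
suite demonstrates the practical consequence: relative prediction errors at
the five lowest levels are strictly smaller under $1/x$ than unweighted on
multiplicative-noise data.

$R^2$ is computed on the weighted fit (weighted residuals against the
weighted mean) and a curve is accepted at $R^2 \ge$ `min_r2`. The default
threshold is 0.995, the stricter of the two conventional acceptance bars;
0.99 is selectable through the same argument.

Curves are linear only. Calibrant levels below a compound's LOD are
retained in the fit; inverse prediction returns negative concentrations
as-is and leaves censoring to the quantitation stage, so no information is
destroyed before the decision point.

## The slope's standard error

The reported `slope_se` is a leverage-adjusted (HC3) sandwich estimate, not
the model-based WLS standard error. The reason is structural: peak-area
noise is multiplicative, so residual variance grows like $x^2$, while
$1/x$ weighting implies the fit "believes" variance grows like $x$. The
model-based standard error then understates the true slope variability by a
factor of about three on this design (verified by simulation in the
acceptance tests, where the robust value tracks the empirical slope
scatter). The robust estimate is what the end-to-end coverage bound uses.

# Sensitivity: LOD/LOQ decision rules

Routine practice determines LOD (S/N ≥ 3) and LOQ (S/N ≥ 10) by visual
inspection of calibrant chromatograms. The package replaces eyeballing
with a deterministic *monotone-suffix scan*: the LOD is the lowest level
whose S/N reaches 3 **and** whose every higher level also reaches 3. An
isolated noise spike at a low level therefore cannot set the LOD below a
level that genuinely fails. This is a deliberate, documented departure
from manual practice; on monotone series the two coincide. When no level
reaches a threshold the run value is "not determined" and never enters the
reference average.

The reference rule: the arithmetic mean of the first five determined run
values per compound is frozen as a reference; thereafter each run reports
`max(run value, reference)`. Both printed branches of the convention —
"apply the average when the run looks better" and "use the higher value
when it looks worse" — are this single expression; the reported limit is
never below an established reference. The reference state persists in
human-readable JSON keyed by compound.

Censoring boundaries are half-open: `below_lod` for $c <$ LOD,
`between_lod_loq` for LOD $\le c <$ LOQ, `quantified` for $c \ge$ LOQ; a
value exactly at the LOQ is quantified. Negative inverse predictions are
`below_lod`.

# Quantitation, units and QC

The gravimetric unit chain is
`ng/L = ng/mL × extract_volume_ml / (mass_g / density / 1000)`.
The default extract volume is 0.5 mL, the final reconstitution volume of
the extraction protocol; the interim evaporation endpoint (~0.125 mL) is
not a separate factor because dilution to the final volume supersedes it.
Density defaults to 1.0 g/mL and the default 100 g aliquot corresponds to
0.1 L, giving a 200-fold preconcentration at 0.5 mL.

QC gates mirror their verbal definitions exactly: accuracy (100 ×
measured/nominal, mean over replicates) passes on the *inclusive* interval
[80, 120]% ("within ±20%"), precision passes at RSD *strictly* below 20%
("below 20%"). A failed gate flags every measurement in the batch
(`qc_pass = FALSE`) but deletes nothing; rejection is an operator decision.

Censored values enter summaries and rates as LOD/2 by default, with
`zero`, LOD/√2 and exclusion selectable. None is statistically innocent;
LOD/2 is the field's customary compromise, and the policy travels as an
explicit argument so sensitivity analyses are one line.

# Recovery evaluation

Extraction efficiency is the ratio of arm means: 100 × mean(spiked before)
/ mean(spiked after), per compound per sorbent, over triplicate
extractions. The per-compound RSD printed next to a recovery is, by
default, the RSD of the *before-spike* replicates — the whole-method
variability — with the RSD of replicate-wise ratios selectable. The choice
matters because a recovery table alone cannot disambiguate which was meant;
the default is stated prominently here for that reason. Efficiencies above
100% are reported as-is; they indicate matrix enhancement. The
ratio-of-means estimator carries a small positive bias of order
$\mathrm{CV}^2/n$ (about 0.3% at CV 10%, $n$ = 3), which the
simulation-based tests bound explicitly.

# Back-calculation

Excretion rate (mg/day per 1000 inhabitants) is
`conc_ngl × flow × 1e-6 / (population / 1000)`; consumption divides by the
biomarker's urinary excretion fraction and, for metabolites, multiplies by
the parent/metabolite molecular-weight ratio. Both are exactly linear in
concentration and flow, which the tests assert as algebraic identities.
Flow may be a per-date record or a site constant; the per-date record wins
when present, since weather and tourism make flow genuinely time-varying.
When both a parent and its metabolite are measured (cocaine and
benzoylecgonine), the metabolite-derived estimate is the preferred
consumption figure — metabolites cannot arrive by direct disposal — and
each biomarker's record names its parent so both remain reported.

Excretion fractions in the packaged panel are literature-shaped defaults,
not measured constants; they vary across populations and studies, and any
serious deployment should replace them with locally curated values. The
panel keeps them as data for exactly that reason. Compounds without a
fraction yield excretion rates but `NA` consumption.

# The synthetic-data generator

`simulate_batch()` emulates the *statistical* structure the pipeline
assumes:

- mean-one lognormal multiplicative noise on every peak area (areas are
  positive and MS area noise is multiplicative), default CV 5%;
- a per-sample matrix suppression factor, uniform on [0.6, 1.2] by
  default, applied equally to native and IS — so the simulator reproduces
  the mechanism that makes isotope dilution work, and an optional
  differential-suppression knob breaks it for stress tests;
- Gaussian additive baseline noise only in the S/N dilution series,
  where `height = slope × level + N(0, sd)`;
- field truths drawn lognormally around a configurable median (default
  500 ng/L, geometric CV 1.0 — magnitudes typical of high-prevalence
  biomarkers in influent wastewater), over a default grid of 17 sites ×
  35 weekly samples.

Because native and IS areas receive *independent* noise draws, a response
ratio carries CV $\sqrt{(1+\mathrm{cv}^2)^2-1} \approx \sqrt{2}\,
\mathrm{cv}$ — about 7.1% at the 5% default. Calibration-level checks use
`simulate_calibration_ratios()`, which places the configured CV directly
on the ratio, the quantity the curve fit actually consumes. The
distinction matters when comparing observed precision against the
configured noise level.

What the generator does **not** emulate: chromatographic peak shape,
retention-time drift, carryover, in-sewer degradation, storage stability,
correlated noise across compounds within an injection, and
population-level temporal structure (trends, weekday effects). Passing
tests therefore demonstrate the correctness and calibration of the
*computations* under the stated error model, not robustness to every
failure mode of real instruments or sewers.

# Numerical choices and degenerate inputs

- Calibration requires ≥ 3 distinct positive levels; zero level variance
  is an error; a flat (zero-slope) series is fitted but never accepted,
  and inverting an unaccepted fit is a refusal error.
- Lognormal noise uses `meanlog = -sdlog²/2` so the noise factor has mean
  exactly 1 and estimators stay unbiased in the small-CV limit.
- All simulation and queue randomness flows through explicit integer
  seeds; generators save and restore the caller's RNG state.
- Ties at censoring boundaries resolve by the half-open convention above.
- Writers emit a fixed column order and `readr`'s full-precision number
  formatting, so identical inputs are byte-identical on disk.

# Problem sizes in the test suite

The suite exercises: 200 seeded 22-level calibrations for the linearity
pass-rate check; 200 seeded single-compound batches for the QC gates;
1000 seeded triplicate recovery experiments; 100 seeded dilution series
for LOD consistency; and 50 seeded three-compound batches (3 sites × 4
weeks each) pooled for the end-to-end coverage check — sizes chosen so
each Monte-Carlo proportion is estimated to about a percentage point while
the whole suite stays interactive.

# Known limitations

- The default panel's internal-standard mapping uses nearest-class
  surrogates where no labelled analog is listed; its transition metadata
  (Q1 placeholder from protonated MW, blank product ions) are
  documentation stubs, not instrument settings.
- No drift or bracketing correction across an injection queue; the queue
  builder randomizes order but the model assumes a stable response within
  a batch.
- No uncertainty propagation over pharmacokinetic constants; consumption
  rates inherit the full bias of the excretion fraction used.
- No population-marker normalization (e.g. ammonium) — population is taken
  from the sites table as served population.
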