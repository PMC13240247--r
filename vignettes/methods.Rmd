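---
title: "Models and methods in caribouscen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in caribouscen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caribouscen)
```

`caribouscen` implements a scenario-based assessment workflow for boreal
woodland caribou ranges: quantify the disturbance footprint of proposed
development, project how habitat selection surfaces respond, and translate
range-level disturbance into demographic outcomes with a stochastic
population projection. This vignette documents the models, the parameters
that matter, the numerical choices, and the limits of what the synthetic
test bed can show.

## Disturbance footprints

A range's disturbance state is summarized by four percentages, measured on
an equal-area grid restricted to cells whose centers fall inside the range
boundary:

* **Anthropogenic** — the union of human features (roads, mines, other
  infrastructure), each dilated by a buffer (default 500 m), as a percent
  of the range.
* **Fire** — area burned within a look-back horizon (default 40 years),
  *not* buffered. Only anthropogenic disturbance carries a buffer; this
  asymmetry is deliberate and matches how these covariates are defined for
  national demographic regressions.
* **Total** — the union of the two footprints.
* **Fire excluding anthropogenic** — burned area outside the buffered
  anthropogenic footprint. Because the union is measured on the same cell
  set, `total = anthro + fire_excl_anthro` holds exactly, by set algebra;
  the test suite asserts it to 1e-9 on randomized fixtures.

Buffering is a Minkowski dilation performed in vector space: each geometry
carries a dilation radius, and rasterization tests cell centers against the
dilated geometry (for lines and points, a distance threshold of
`max(buffer, half cell diagonal)`; the half-diagonal floor makes thin lines
register on coarse grids and keeps the rasterized footprint monotone in the
buffer width). No union or offset polygons are ever constructed, so
footprints of overlapping features cannot double-count. The default
analysis resolution is 250 m — small enough that the default 500 m buffer
spans at least two cells — and is configurable everywhere.

The membership rule (cell centers) and the resolution are choices the
percentages depend on; with other conventions the same inputs can shift by
a few hundredths of a percent. The package states the rule explicitly
rather than leaving it implicit in a GIS toolchain.

## Resource selection surfaces

Habitat selection is projected from *published coefficient tables*, not
refit: a table holds one linear-predictor term per habitat covariate for a
given range and season. Predictor rasters are derived from the landscape
and scenario:

* moving-window proportions of each land-cover class (circular window,
  default 5 km radius — the window and radius are configurable because the
  original models' exact definitions vary by source publication);
* road density, km of road per km^2 of window, computed from exact per-cell
  road lengths (Liang–Barsky clipping of each segment to each cell);
* distance to the nearest road, km.

The surface is `w = exp(eta)` rescaled by its maximum over valid cells, the
standard exponential RSF form, so values live on (0, 1] and the best cell
scores 1; a logistic transform is available for coefficient sets fit as
use–availability logistic regressions. Max-rescaling makes the exponential
surface exactly invariant to adding a constant to `eta` (asserted to 1e-12
in the tests), which is why only relative, within-surface comparisons are
meaningful. Cells missing any predictor propagate to nodata.

Transferability of a model between ranges is diagnosed cell-wise: pair the
reference and transferred surface values on their shared valid cells,
report Pearson's r, and keep the pairs for a scatterplot. Zero-variance
surfaces make r undefined; the report flags this explicitly instead of
returning a number.

The shipped coefficient table (`rsf_coefficients_illustrative.csv`) is
synthetic: it has the qualitative structure of published boreal caribou
tables — peatland and conifer selection, avoidance of open water, a strong
negative road-density response in one range's spring/summer models and an
order-of-magnitude weaker response elsewhere — but not the published
values, which users must transcribe from the source publications (error
estimates for those coefficients were never published, so no uncertainty
propagation is attempted).

## Disturbance–demography model

Expected adult female survival and recruitment are beta regressions on the
two disturbance covariates:

* survival: logit link by default, `S_bar = plogis(b0 + b1 * anthro + b2 *
  fire_excl)`;
* recruitment: log link by default on the calves-per-100-cows scale,
  divided by 100 internally so all demographic arithmetic runs in calves
  per cow.

Links are configurable per block because different published fits use
different scales. Survival predictions outside (0, 1) are clamped with a
warning (identity-link configurations can produce them); negative
recruitment is an error.

The expected growth rate of the adult-female segment is the Hatter–Bergerud
female-only form under a 50% calf sex ratio:

    lambda_bar = S_bar * (1 + R_bar / 2)

This identity is exact in the code (it is the definition, not a fit).

**Among-population variation** uses the beta distribution's mean/precision
parameterization, `alpha = mu * phi`, `beta = (1 - mu) * phi` — stated here
to remove shape-parameter ambiguity. Each sample population is assigned
quantiles `(q_S, q_R)` of the among-population distributions and *keeps
them as disturbance changes* (quantile persistence). Consequences, all
tested: trajectories of different populations never cross over a
disturbance gradient (comonotonicity); the mean over i.i.d. quantiles
recovers the expected rate; and the 2.5–97.5% band of sampled rates is the
analytic beta predictive interval. Stratified sampling (one draw per
equal-probability bin) is the default so small ensembles cover the
distribution; bins are independently permuted between survival and
recruitment, which keeps `q_S` and `q_R` unrelated — their joint
correlation is not identified by the published models, so independence is
the default and a flag can force `q_S = q_R`.

The shipped demographic model (`demographic_model_illustrative.yaml`) is
likewise synthetic-but-shaped-right: both rates decline with anthropogenic
disturbance, survival near 0.90 and recruitment near 28 calves per 100
cows at low disturbance, with among-population precisions (60 survival, 15
recruitment) chosen so rate variability among populations is large relative
to the scenario effects — the regime in which range-specific projection
from a national model is genuinely uncertain.

## Stochastic population projection

One population's trajectory is a yearly loop over adult females with three
optional stochastic layers:

1. **Interannual variation**: annual `S_t`, `R_t` drawn from beta
   distributions around the population means, with their own precisions
   (defaults 400 and 60; year-to-year noise is smaller than
   among-population spread).
2. **Demographic stochasticity**: survivors `~ Binomial(N_t, S_t)`;
   recruited females `~ Binomial(survivors, min(R_t/2, 1))`. Recruitment
   applies to survivors, and the per-capita female-calf probability is
   clamped at 1 so the binomial stays well defined at extreme draws.
3. **Density dependence**: a hard ceiling `K = c * N0` (default `c = 5`).
   The published description names density dependence without a functional
   form; a ceiling is the simplest form that cannot distort sub-ceiling
   growth, which the identity tests rely on.

With layers 1–2 off the skeleton is deterministic and reproduces
`lambda_bar` exactly below the ceiling (tested to 1e-9). Extinction is
absorbing. The realized growth rate is the geometric mean
`(N_T / N_0)^(1/T)`, zero for extinct trajectories.

Defaults the source description leaves open, fixed here once: a 20-year
horizon and 100 initial females. These are conventional round numbers for
boreal caribou assessment-scale projections; both are arguments, not
constants. Ensembles default to 500 sample populations, each on its own
RNG stream (`seed + population index`), so results are reproducible and
independent of evaluation order; quantiles are drawn once and shared across
scenarios so scenario contrasts are paired. A population whose realized
growth falls below 0.99 is counted as not self-sustaining.

## Synthetic landscapes and calibration

The generator exists so the full workflow runs and is testable with no
external data. It emulates the *structure* of a boreal range:

* categorical land cover with spatially autocorrelated patches, produced by
  slicing one Gaussian-smoothed noise field at the empirical quantiles of
  the target class proportions (any patch-producing, seed-deterministic
  process would do; this one also hits the proportions to within cell
  rounding);
* an irregular range boundary (a low-order harmonic perturbation of a
  circle);
* dated burn polygons accumulated until a target burned fraction;
* nested development scenarios: meandering west–east road polylines drawn
  from a fixed pool (a longer network geometrically contains a shorter
  one) and mining-claim polygon blobs anchored on the roads.

Scenario calibration finds, by bisection, the road length — and then the
number of mine blobs — whose *buffered* footprint hits a target percentage
of the range (tolerance ±0.5 points). The mine knob is a continuous
"budget": whole blobs plus a shrunken fractional last blob, because the
buffer puts a floor (roughly `pi * buffer^2`) under the footprint of any
polygon however small, and calibrating blob *size* alone cannot cross that
floor smoothly. The default targets (0.41%, 1.11%, 16.91%) bracket the
staged-development magnitudes reported for low-disturbance northern
ranges, so the demographic scenarios run at realistic covariate values.

What the synthetic test bed does **not** show: ecological realism
(hydrology, succession, fire aging of forest structure), real predictor
provenance, or observation error in demographic data. Passing tests
demonstrate that the computational machinery is correct and internally
consistent — not that any particular range's published numbers will be
reproduced, which requires the real GIS inputs and transcribed published
coefficients.

## Numerical choices and degenerate inputs

* Moving windows use FFT convolution; window means exclude nodata from both
  numerator and denominator, and cells with no valid neighbour become
  nodata. FFT round-off is at the 1e-10 level and tests compare against
  brute-force window sums at 1e-6.
* The exponential RSF subtracts `max(eta)` before exponentiating, so large
  linear predictors cannot overflow.
* Polygon interiors use the even-odd rule; self-intersecting rings are
  flagged with a warning and processed under that rule rather than
  rejected.
* Degenerate comparisons (fewer than 3 shared valid cells, zero-variance
  surfaces) are errors or explicit flags, never silent numbers.
* Problem sizes in the test suite are deliberately small (20 km synthetic
  ranges at 250 m, ensembles of tens to hundreds of populations; the
  acceptance script uses a 40 km range and 500 populations over 20 years),
  chosen so the whole suite exercises every code path in a few minutes.

## Command line

`inst/cli/boreal.R` is a thin Rscript over the exported functions:
`synth` writes seeded landscape/scenario fixtures (ASCII grid + GeoJSON +
truth JSON), `disturbance` tabulates the four percentages, `rsf` and
`rsf-compare` project and compare surfaces, `demography` samples
population-level rates, `simulate` runs scenario ensembles, and `run`
executes the full pipeline from a YAML config with a manifest (seed,
parameters, output checksums) for reproducibility. Exit code 2 signals a
validation error before any computation.

## Known limitations

* No refitting to telemetry or survey data, no model selection, no
  uncertainty in the regression coefficients themselves (point coefficients
  in, point expected rates out; all spread comes from the beta layers).
* The female-only projection ignores age structure beyond adult/calf, male
  dynamics, harvest, and movement.
* Published percentages for a real range can only be matched by supplying
  the real GIS layers and matching the original workflow's rasterization
  conventions; the cell-center rule at 250 m is one defensible convention,
  not the only one.
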