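---
title: "Methods: spatial exposure assessment and matched case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial exposure assessment and matched case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The study design

`spatcc` implements a GIS-based case-control analysis of residential
environmental exposures and childhood central nervous system (CNS) tumors,
and a synthetic-landscape simulator that makes the whole analysis testable
end-to-end against known truth.  The design it reproduces is a
population-based registry study: incident cases (ICCC-3 Group III, ages
0-14) are individually matched to six controls each on sex, birth year and
autonomous region of residence, and three exposures are derived from the
geocoded residence:

* **Crop exposure (GCI).**  The Global Crop Index is the percentage of
  cultivated land inside a 1-km circular buffer around the residence, summed
  over six land-cover subcategories (irrigated arable land, rice, vineyards,
  fruit trees, olive groves, heterogeneous agricultural areas).  The model
  covariate is GCI/10, so a unit coefficient exponentiates to the odds ratio
  per 10-percentage-point increase in cultivated land.
* **Industrial/urban environment.**  Each residence is classified into one
  of five mutually exclusive categories from the distance `d` to the nearest
  industrial facility and membership in an urban polygon:
  *intersection* (urban, `d <= D`), *industrial* (non-urban, `d <= D`),
  *urban* (urban, `d > D`), *ring* (non-urban, `D < d <= 5 km`) and
  *rural* (non-urban, no facility within 5 km; the reference).  `D`
  defaults to 2 km; `d_sweep()` refits the model over a list of candidate
  distances (default 1, 1.5, 2, 2.5, 3, 4, 5 km) to show the sensitivity of
  the environment odds ratios to `D`.  No change-point detection is
  performed on the sweep; the table is meant for inspection.
* **Socioeconomic status (SES).**  Each residence inherits the "socioeconomic
  condition" value of its census tract (values spanning roughly 0.46-1.57,
  higher = less deprived), categorized into quartiles; Q4-vs-Q1 is the
  headline contrast.

The association model is a **mixed unconditional logistic regression**: case
status on environment category, SES quartile, GCI/10, sex and birth year,
with a zero-mean normal random intercept per region.  The matched design is
analysed unconditionally with the matching factors as covariates (not by
conditional likelihood), exactly as in the reference design.  Confidence
intervals are Wald intervals, `exp(estimate ± 1.96 SE)`; profile intervals
are deliberately not used so that intervals match the reporting convention.

## The synthetic landscape generator

No registry, census or land-cover data are distributed, so every analysis
stage is exercised against `generate_landscape()` / `generate_population()`
/ `assign_outcomes()`:

* **Land cover** is a jittered rectangular partition of the square study
  extent with i.i.d. category labels.  Cells default to roughly 1 km
  (`n_cells = 2500` over 50 km), matching the granularity of the European
  land-cover inventory the design emulates, and keeping regional exposure
  means stable (very coarse cells make narrow regions effectively
  single-category, which clusters cases into few matching strata).  Default
  mixture weights put 45% of the land under crops, dominated by irrigated
  and heterogeneous classes, as in the agricultural regions the study
  covers.  Tests never depend on cell shapes, only on the partition
  invariants (areas sum to the extent; no overlaps by construction).
* **Facilities** are a uniform point process (default 40 over 50 × 50 km,
  which yields a realistic ~10-15% rural reference share at the default
  thresholds).
* **Urban areas** are squares sized proportionally to log-normal populations
  (median 20 000, 250 m² per inhabitant); polygons with population below
  10 000 do not count as "urban" in the classification, reflecting a
  municipality-size definition of urban areas.
* **Tracts** are a second, finer partition (default 400) with SES drawn
  uniformly on 0.46-1.57, the printed range of the census variable.
* **Regions** are vertical bands with widths proportional to the configured
  region marginal (default: the registry's case shares over Aragon,
  Catalonia, Madrid, Navarre and the Basque Country).  A subject's region
  label is drawn from the marginal and its residence placed inside the
  band — 70% inside a population-weighted urban polygon of the band,
  30% uniform.  2% of subjects get invalid geocodes (`NA` coordinates),
  mirroring the geocoding failure rate; matching replaces them in-stratum.
* **Outcomes** follow the logistic model the analysis fits:
  `logit p = intercept + log(1.22)·GCI/10 + SES and environment terms +
  region intercept`.  The default true odds ratios are the reference
  full-study adjusted point estimates (GCI 1.22 per 10 points; SES
  Q2/Q3/Q4 0.97/1.01/1.37; industrial/intersection/urban
  0.96/1.20/0.90; the non-urban ring, sex and year null).  With the default
  baseline log-odds of −7 the outcome is rare everywhere, so drawing exactly
  `n_cases` cases by weighted sampling without replacement (a registry of
  fixed size) is equivalent to sampling proportionally to the exposure odds.
  By default the per-region case totals are fixed at the region marginal
  (largest-remainder allocation, sampling within regions still
  probability-weighted), because the registry design being emulated has a
  fixed regional case distribution and region-matched controls presuppose
  it; `stratify_cases_by_region = FALSE` restores fully global sampling.
  The region intercept SD defaults to 0.15 — modest regional heterogeneity;
  it is largely absorbed by the matched design, which is also why fitted
  region variances often land on the boundary (see below).  Case subgroup
  labels are multinomial with the registry shares and independent of
  exposure.
* **Residential mobility.**  After outcomes are assigned, a configured
  fraction of cases (default 53.5%, leaving 332 of 714 cases at their birth
  address) moves to a fresh, exposure-independent residence in the same
  region.  The main analysis measures movers at the diagnosis address —
  deliberately reproducing the exposure-misclassification bias of
  diagnosis-address studies — while `same_address_sensitivity()` refits on
  non-movers plus all controls.  Parameter-recovery runs set
  `mover_fraction = 0` so that the analysed exposure is the causal one and
  the generating odds ratio is the estimand.

Everything is a pure function of `(config, seed)`; stage seeds are derived
from the run seed, and `run_study()` re-produces byte-identical outputs.

### What the generator does *not* emulate

Real geography (street networks, coastlines, actual Spanish land use),
spatially autocorrelated SES, exposure-correlated migration, and
facility-type-specific emission profiles.  Passing recovery tests therefore
demonstrate that the *estimator and pipeline* are correct under the stated
data-generating process, not that the reference study's substantive findings
are reproduced from real data — those inputs are confidential.

## Numerical and design choices

* **Geometry.**  Buffers are regular 64-segment polygons; the polygon's own
  area is the denominator of the area fractions, so full containment gives
  exactly 100 and the polygonization error (0.16% of the area) cancels.
  Buffer–polygon intersection areas are computed by Sutherland–Hodgman
  clipping against the convex buffer (correct for non-convex land-cover
  polygons) with bounding-box prefilters and a fully-inside shortcut; an
  independent Monte-Carlo estimator (`crop_index_oracle()`, uniform points
  in the disc + ray-casting membership, SE ≤ 0.5 points at 10⁵ samples)
  cross-checks it in the tests.  Buffers may extend past the mapped extent;
  the unmapped part counts as non-crop and the denominator stays the full
  buffer area (conservative and reproducible).
* **Malformed land cover.**  Overlapping polygons would double-count area;
  `crop_index()` detects totals exceeding the buffer area and falls back to
  a deterministic Monte-Carlo union estimate with a warning.  Valid
  partitions always take the exact path.  (Exact polygon union without a
  computational-geometry dependency is out of scope.)
* **Boundary conventions.**  `d <= D` is exposed; `d > 5 km` is rural; a
  point on an urban-polygon boundary is inside; a point on a shared tract
  edge resolves to the first tract in layer order.  Urban subjects never
  fall in the ring (the ring is defined outside urban areas); "far from
  urban areas" is implemented as outside all urban polygons, with an
  optional urban buffer parameter (default 0).
* **SES quartiles** use type-7 (linear-interpolation) percentiles of the
  reference distribution — controls by default, so control counts split into
  near-equal quarters; a configuration switch allows the whole study as
  reference.  Labels use half-open intervals `[q25, q50)` etc., values
  outside the reference range clamp to Q1/Q4.  Because SES is constant
  within a tract, ties can make the quarters deviate from `n/4` by up to a
  tie-block; with distinct values the split is exact to ±1.
* **Matching** draws controls uniformly without replacement within the
  (sex, birth year, region) stratum, first from the full stratum and then
  replacing any invalid geocodes from the same stratum; controls are never
  reused across cases, so 714 cases yield exactly 4284 distinct controls.
  Birth year matches exactly by default; a window parameter exists because
  the original design does not state one.
* **Model fitting** uses `lme4::glmer` (Laplace by default, `nAGQ`
  configurable).  A random intercept over five regions is fragile: on
  singular fits (variance at the zero boundary — the expected outcome under
  matching, which equalizes the case:control ratio within regions) the fit
  automatically falls back to ordinary logistic regression with region as a
  fixed factor, recorded in `$method` and `$notes`.  With a single region
  the fit is plain `glm` and agrees with ordinary logistic regression to
  machine precision.  Birth year enters as a centered linear term by default
  (categorical option available).  Missing covariates are handled
  complete-case with the drop count recorded.
* **Leave-one-region-out.**  Because matching fixes each region's
  case:control ratio, region-level confounding is structurally impossible in
  the simulated design: excluding an exchangeable region leaves the crop OR
  within Monte-Carlo error of the full fit, which is what the tests assert.
  The generator still exposes per-region knobs (`region_crop_weights`,
  `region_ses_range`) to build crop-free, high-SES regions for descriptive
  sweeps.

## Problem sizes used in the tests

Unit tests run on 20-km landscapes with ~100 cells and pools of a few
thousand subjects.  The calibration and recovery checks use: 100 replicates
at the full study scale (714 cases, 4284 matched controls, pool 45 000) for
parameter recovery — mean recovered GCI OR within ±0.05 and SES Q4 OR within
±0.05 of truth, 90-99% Wald coverage — and 200 replicates of a smaller null
study (120 cases, pool 6 000, all true ORs 1) for coverage under the null.
These sizes give Monte-Carlo standard errors comfortably inside the asserted
tolerances (the SE of the mean recovered GCI OR is about 0.002).

## Worked example

```{r example}
library(spatcc)

config <- study_config(mover_fraction = 0,
                       analyses = c("main", "sweep", "regions"))
report <- run_study(config, seed = 1)
print(report)

# the main odds-ratio table (counts, percentages, OR, 95% CI per category)
head(report$table_main, 12)

# sensitivity of the environment ORs to the industrial distance D
report$sweep
```

## Known limitations

* The isotropic buffer ignores wind, terrain and waterways; like the design
  it reproduces, exposure misclassification is towards the null.
* Polygon holes and multi-polygons are not supported in the GeoJSON layers.
* The region random intercept is estimated from only five levels; rely on
  the fixed-effects fallback diagnostics for inference about regions.
* The Monte-Carlo union fallback for overlapping land-cover input is an
  estimate (SE well under one percentage point), not an exact area.
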