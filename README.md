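# spatcc

Spatial exposure assessment and matched case-control analysis on synthetic
landscapes.

`spatcc` is an R package for the GIS-based epidemiology workflow used in
registry studies of childhood central nervous system (CNS) tumors and
residential environment: it derives exposure covariates from geocoded
residences, builds the matched case-control data set, and estimates adjusted
odds ratios with mixed-effects unconditional logistic regression.  Because
the registry, census and land-cover inputs of such studies are confidential,
the package ships a synthetic-landscape and population generator with a
configurable logistic outcome model, so the entire pipeline can be validated
end-to-end against known true odds ratios (null calibration and parameter
recovery).

## What it computes

For each residence with planar coordinates `(x, y)`:

* **Global Crop Index (GCI)** — the percentage of cultivated land inside a
  1-km circular buffer, plus the six crop subcategory indices (irrigated,
  rice, vineyards, fruits, olives, heterogeneous).  The model covariate is
  `GCI/10`: its exponentiated coefficient is the OR per 10-percentage-point
  increase in cultivated land.
* **Industrial/urban/rural environment** — five mutually exclusive
  categories from the distance `d` to the nearest industrial facility and
  urban-polygon membership (threshold distance `D = 2 km`, outer rural
  threshold 5 km): intersection (`urban, d ≤ D`), industrial
  (`non-urban, d ≤ D`), urban (`urban, d > D`), ring
  (`non-urban, D < d ≤ 5 km`) and rural (reference).  `d_sweep()` refits the
  model across `D ∈ {1, 1.5, 2, 2.5, 3, 4, 5} km`.
* **SES quartile** — the census-tract socioeconomic value of the containing
  tract, categorized by control-based quartiles (Q4 vs Q1 is the headline
  contrast).

Controls are individually matched 6:1 on sex, birth year and region, with
in-stratum replacement of invalid geocodes, and the model

```
logit P(case) = β₀ + β_env + β_ses + β_gci·GCI/10 + β_sex + β_year + u_region,
u_region ~ N(0, σ²)
```

is fitted by `lme4::glmer` (Wald 95% CIs; automatic fixed-effects-region
fallback on boundary variance fits).

## Worked example

```r
library(spatcc)

config <- study_config(mover_fraction = 0, analyses = c("main", "sweep"))
report <- run_study(config, seed = 1)
print(report)
```

```
<study_report>
<study_data> 714 cases + 4284 matched controls (pool 45000), seed 1
  main model (glm_region_fixed): GCI OR per 10 points = 1.227 (1.186, 1.269)
  SES Q4 vs Q1 OR = 1.497 (1.185, 1.891)
  sections: table_main, sweep
```

The simulation generated outcomes with a true GCI OR of 1.22 per 10 points
and a true SES Q4 OR of 1.37 (the package defaults); this replicate recovers
1.227 with a Wald interval covering the truth, and the Q4 interval
(1.185, 1.891) likewise covers 1.37.  The fit method is reported alongside:
here the region variance hit the zero boundary (the expected outcome under
region matching) and the model automatically refit with fixed region
effects.  `report$table_main` holds the
full odds-ratio table (per-category case/control counts and percentages, OR,
95% CI, and the count of subjects with GCI > 0); `report$sweep` holds the
environment ORs refitted at each candidate industrial distance `D`.

Individual stages are exported for piecewise use: `generate_landscape()`,
`generate_population()`, `assign_outcomes()`, `crop_index()` (with its
Monte-Carlo oracle `crop_index_oracle()`), `classify_environment()`,
`assign_ses()` / `ses_quartiles()`, `match_controls()`,
`fit_mixed_logistic()`, `crude_or()`, `same_address_sensitivity()` and
`leave_one_region_out()`.  Layers are exchanged as GeoJSON
(`read_geojson()` / `write_geojson()`), subjects as CSV, configurations as
YAML; `inst/cli/run_study.R` is a thin command-line wrapper over
`run_study()`.

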