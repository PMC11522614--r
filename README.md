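# pollcontrib

Do the species we rely on for crop pollination respond differently to
human land use than the species we do not? `pollcontrib` implements a
species-level **ecosystem service contribution matrix** — importance for
crop pollination × certainty of the evidence → low/medium/high
contribution group — and the hierarchical modelling pipeline needed to
ask that question with PREDICTS-style assemblage surveys: inclusion
filters and site merging, an 18-category land-use × use-intensity
disturbance axis, capped percentages of semi-natural habitat (SNH)
around each site from categorical land-cover rasters, Poisson/Gaussian
mixed-effects models with backwards stepwise likelihood-ratio selection,
and a sensitivity suite. A synthetic-data generator with known ground
truth makes every stage recovery-testable.

It is aimed at ecologists and biodiversity modellers who want to carry
interspecific differences in service provision through an assemblage
analysis instead of pooling "pollinators" into one bag.

## The core objects

* **Contribution matrix** — an editable YAML grid over ordered
  importance levels (negligible → very high; driven by how dependent
  the pollinated crops are on animal pollination) and certainty levels
  (evidence strength and taxonomic resolution). Cells map to
  low/medium/high groups; the map must be monotone along importance.
  When several cells are admissible for a species, the higher
  contribution wins, so evidence can never demote a species.
* **Models** — richness: `richness ~ group * lui + (1|study) +
  (1|block) + (1|site)` (Poisson; the site term absorbs overdispersion,
  and a quasi-likelihood adjustment scales standard errors by the
  Pearson dispersion when it exceeds 1); total abundance:
  `log(x+1) ~ group * lui * snh + (1|study) + (1|block)` (Gaussian,
  ML). Effects are reported as percentage differences relative to
  minimally used primary vegetation, `100(e^{Δη} − 1)`, with
  delta-method standard errors.
* **SNH** — `100 · Σ a_c s_c κ_c / (100 Σ a_c)` over raster cells whose
  centres fall within a great-circle radius (1 km by default): `s_c`
  flags forest/grassland/wetland/shrubland, `κ_c` is the category's
  maximum-cover cap parsed from its legend label (an "open (15%–40%)"
  forest caps at 40, a closed one at 100), `a_c` the geodesic cell
  area.

## Worked example

```r
library(pollcontrib)

cfg <- sim_config(n_studies = 24, blocks_per_study = 2, sites_per_block = 6,
                  n_species = 50, seed = 7)
ds  <- simulate_surveys(cfg)
ds
#> synthetic_dataset: 24 studies, 288 sites, 50 species ( 27/17/6 low/med/high ),
#> 14400 assemblage rows

st <- run_pipeline(ds$assemblage, ds$evidence,
                   raster = ds$raster, legend = ds$legend)

st$fits$richness
#> fitted_model: poisson response = richness | n = 864 | logLik = -1634.18 |
#> converged = TRUE | dispersion = 0.388
#> fixed effects:
#> (Intercept)   grouphigh groupmedium
#>      1.9469     -0.8977     -0.5594

tab <- predict_relative_table(st$fits$abundance)
subset(tab, lui == "cropland intense")
#>                 lui  group snh_pct pct_diff se_pct
#> 2  cropland intense    low    31.6    -70.9   4.35
#> 20 cropland intense   high    31.6     40.8  21.06
#> 38 cropland intense medium    31.6    -36.3   9.53
#> ...
```

Reading the output: the pipeline filtered and merged the survey,
classified each species through the contribution matrix (the round trip
back to its assigned cell is exact by construction), dropped orders not
present in all three groups, aggregated per-site per-group richness and
total abundance, extracted SNH from the synthetic raster, and fitted
both models with backwards selection. In this simulation the abundance
of low-contribution species in intensely used cropland is about 71%
below minimally used primary vegetation, while high-contribution
species are about 41% *above* it — the kind of group-dependent response
the pipeline is built to detect. The richness selection kept only the
group term here: with 864 observations spread over 18 disturbance
categories, the 34-df interaction is underpowered at this problem size,
and the trace in `st$selection$richness` records exactly that decision.

Sensitivity tools: `chao1_metrics()` (richness corrected for incomplete
sampling), `remove_outliers()` (`O > Q3 + 1.5·IQR` on pooled
abundances), `loo_by_study()`, `morans_i_by_study()` (inverse-distance
Moran's I per study), `zero_audit()`, and `rerun_importance_only()`
(regroups species by the high-certainty row of the matrix and refits).

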