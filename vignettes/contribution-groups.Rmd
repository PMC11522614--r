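---
title: "Contribution groups, land use and surrounding habitat: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contribution groups, land use and surrounding habitat: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pollcontrib)
```

# The question and the model

Terrestrial species differ enormously in how much they contribute to crop
pollination, and crops differ in how much they depend on animal
pollination: losing a confirmed pollinator of pollination-essential crops
is not the same event as losing an occasional flower visitor. This
package asks whether species with different crop-pollination
contributions respond differently to land-use type, land-use intensity,
and the amount of semi-natural habitat (SNH) around a site, using
hierarchically structured assemblage surveys (sources > studies > spatial
blocks > sites) of the kind collected in global land-use biodiversity
databases.

The analysis proceeds in five stages, each an exported module:

1. **Contribution matrix** (`classify_species()`, `load_matrix()`):
   every species receives an *importance* level (negligible to very
   high, driven by the dependence of the crops it pollinates on animal
   pollination) and a *certainty* level (low/medium/high, driven by the
   strength and taxonomic resolution of the evidence). The matrix cell
   maps to a low/medium/high **contribution group**.
2. **Preparation** (`filter_records()`, `merge_sites()`,
   `combine_lui()`, `balance_orders()`, `site_metrics()`): inclusion
   filters, duplicate-site merging, the 18-category land-use ×
   use-intensity disturbance axis, order balancing, and per-site
   per-group species richness and total abundance.
3. **Landscape** (`snh_percentage()`): capped percentage of SNH within a
   radius of each site, from a categorical land-cover raster and legend.
4. **Models** (`fit_glmm()`, `backwards_select()`,
   `overdispersion_adjust()`, `predict_relative()`): a Poisson GLMM of
   richness and a Gaussian LMM of `log(x+1)` total abundance, with
   backwards stepwise likelihood-ratio selection and quasi-likelihood
   overdispersion adjustment.
5. **Diagnostics** (`chao1()`, `remove_outliers()`, `loo_by_study()`,
   `morans_i()`, `zero_audit()`, `rerun_importance_only()`): the
   sensitivity suite.

A synthetic-data generator (`simulate_surveys()`) emulates all the
inputs with known ground truth, so every stage is testable by parameter
recovery.

# The contribution matrix

The matrix is data, not code: `load_matrix()` reads a YAML grid and
validates that the cell map is complete and that contribution never
*decreases* as importance rises at fixed certainty. The default shipped
grid is:

```{r}
default_matrix()
```

Evidence records propose candidate cells. Crop-pollinator records carry
a multiset of per-crop dependence levels
(essential/great/modest/little/none); the importance level is set by the
strongest dependence class covering **more than half** of the crops
(e.g. "great" for over half of crops → high importance), and certainty
rises with true-pollinator (versus floral-visitor) status and with
species-level (versus genus-level) resolution. Genus-level pollinator
listings carry a four-level confidence score, mapped 4 → high certainty,
2–3 → medium, 1 → low, and propagate to every species of the genus by a
name-prefix join; broad non-taxonomic categories are expected to be
excluded upstream. When several cells are admissible the species gets
the cell with the **higher contribution group** (ties towards higher
importance, then certainty), so adding evidence can never demote a
species — a property the test suite checks by exhaustive pairwise
evidence addition. A species with no evidence is classified at
negligible importance (lowest certainty) rather than rejected.

The importance-only sensitivity view (`importance_only_group()`) reads
every species off the highest-certainty row, so importance is not
down-weighted by evidential uncertainty.

**Limitations.** The default grid is an editable transcription; cell
rules for other ecosystem services can be substituted without touching
code. Importance is assumed spatially and intraspecifically constant —
there is no data support for more.

# Preparation choices

* Binomials must have a genus and a specific epithet, with no
  uncertainty markers (`sp.`, `cf.`, `?`, ...).
* Sites merge when they share study, coordinates (compared after
  normalisation to 6 decimal places — a database-key notion of
  equality, not a geodesic tolerance), sampling method, sampling dates,
  land use and intensity. Abundances sum; occurrences OR.
* The disturbance axis is the full 6 × 3 cross product (18 categories),
  with *minimally used primary vegetation* as the reference everywhere.
* Orders that do not span all three contribution groups are dropped, so
  group contrasts are not confounded with pure taxonomy.
* A (site, group) pair contributes a zero-richness record only when the
  site's study sampled at least one taxon from that group's orders:
  absence outside a study's taxonomic scope is not a zero.
* Occurrence-only sites are retained for richness and excluded from
  abundance models.

# Surrounding semi-natural habitat

`snh_percentage()` classifies legend labels into SNH (forest, grassland,
wetland, shrubland) versus everything else, and parses each label's
parenthesised cover range: an "open (15%–40%)" class can occupy at most
40% of a cell, so a disc filled with it yields 40%, while a closed
(">40%") class caps at 100. The estimate is

$$\mathrm{SNH\%} = 100 \cdot
\frac{\sum_{c \in \mathrm{disc}} a_c\, s_c\, \kappa_c / 100}
     {\sum_{c \in \mathrm{disc}} a_c},$$

where \(a_c\) is the cell's geodesic area (cos-latitude weight on a
regular degree grid), \(s_c\) the SNH flag and \(\kappa_c\) the cap. A
cell belongs to the disc when its **centre** lies within the
great-circle radius of the site — the same mask a per-pixel enumeration
uses, which is why the test suite can demand agreement with a
brute-force oracle at `1e-9` relative tolerance. At a 300-m-class
resolution and a 1-km radius the centre-in/out rule differs from exact
area-of-intersection weighting only in the boundary ring; the difference
vanishes as resolution refines and is far below the thematic uncertainty
of any land-cover product. Caps apply to the numerator only: they limit
how much SNH a category can contribute, not how much landscape exists
(`cap_denominator = TRUE` switches to the other reading). The default
radius is 1 km (a common dispersal-distance proxy); 10 km and 50 km are
the sensitivity radii.

Rasters are in-memory integer grids (`lc_raster`) with a plain-text
georeferenced interchange format (ESRI ASCII grid, `read_asc()` /
`write_asc()`), so fixtures and synthetic landscapes are fully
reproducible from code.

# The two models

**Richness**: Poisson GLMM, `richness ~ group * lui + (1|study) +
(1|block) + (1|site)`. The site intercept is the observation-level
device that absorbs extra-Poisson variation. After fitting, the Pearson
dispersion ratio \(\hat\varphi = \sum r_i^2 / \mathrm{df}\) is
estimated; when \(\hat\varphi > 1\) the coefficient covariance is scaled
by it (quasi-likelihood adjustment), leaving point estimates untouched.
SNH is *not* in the default richness model: with 18 categories and an
observation-level intercept the full interaction structure is generally
not estimable, so it is exposed as an ordinary optional term instead.

**Total abundance**: Gaussian LMM on `log(x+1)`, full fixed structure
`group * lui * snh` (all 2- and 3-way interactions) with study and block
intercepts, fitted by ML so that likelihood-ratio tests between fixed
structures are valid. SNH enters as a fraction centred at its sample
mean over the modelled rows.

**Selection** (`backwards_select()`): repeatedly drop the currently
droppable term (marginality respected: a main effect cannot leave while
a containing interaction remains) with the largest LRT p-value above
`alpha = 0.05`; ties break towards the higher-order term, then
lexicographically, making the trace deterministic. The outcome in which
every candidate survives selection is simply the case where no droppable
term tests above `alpha`. Both `alpha` and the
marginality policy are explicit arguments/design choices — neither is
dictated by the method itself.

**Effects on the outcome scale** (`predict_relative()`): results are
percentage differences relative to minimally used primary vegetation
within the same group, `100(e^{\Delta\eta} - 1)`, with delta-method
standard errors from the (possibly dispersion-scaled) covariance. For
the abundance model the contrast is on the `log(x+1)` scale, so the
back-transform is multiplicative in `x + 1` rather than `x`; this is a
documented approximation, exact for the Poisson/richness scale.
`predict_relative_table()` evaluates every category × group at the
33rd/66th SNH percentiles of the data at hand (low/high SNH), with the
high percentile as the reference condition.

# The synthetic generator

`simulate_surveys()` draws studies on disjoint 0.25° tiles, blocks as
disjoint strips, sites uniform within blocks (so per-study spatial
statistics are well defined); a categorical land-cover raster at 0.003°
(≈330 m, the resolution class of global products) over the whole domain;
and per-species site counts

$$y_{sp,site} \sim \mathrm{Pois}\!\big(\exp(\beta_0 +
\beta_{\mathrm{lui}, g(sp)} + \gamma_{\mathrm{lui}, g(sp)}\,
\mathrm{SNH}_{site} + u_{study} + u_{block} + u_{site})\big),$$

zeroed with probability `zero_inflation_prob`. Key properties, all
tested:

* **Internal consistency**: richness and total abundance are computed
  from the same counts, as in real assemblage databases.
* **SNH is not a dial**: each synthetic site's SNH comes from the
  synthetic raster through the same `snh_percentage()` the analysis
  uses.
* **Evidence round trip**: each species is assigned a realisable matrix
  cell and `simulate_evidence()` emits a canonical evidence set that
  classifies back to exactly that cell (occasionally plus a strictly
  dominated weaker record, which the tie-break must ignore).
* **Determinism**: the dataset is a pure function of the config,
  including the seed, and the caller's RNG stream is untouched.

Defaults: 20 studies × 2 blocks × 4 sites, 60 species split 60/25/15%
across low/medium/high groups, random-intercept SDs 0.5/0.3/0.2
(decreasing down the hierarchy, as typically estimated for such data),
baseline log abundance 1, zero inflation 0.2 (real abundance tables
carry a zero share of roughly this order), and an illustrative
qualitative effect pattern: low-contribution species decline with
disturbance and intensity, high-contribution species respond less
negatively or positively in cropland/pasture/urban. No published
link-scale effect sizes exist for these groups, so the defaults are
illustrative rather than calibrated; every recovery test states its own
effects explicitly.

What the generator does **not** emulate: phylogenetic or trait
structure, temporal dynamics, uneven sampling effort, taxonomic
misidentification, spatially autocorrelated habitat selection. Passing
recovery tests therefore demonstrates the estimators are correct under
the stated model, not that the model captures every feature of real
surveys.

# Calibration designs and numerical choices

Two frozen designs (chosen at design time, stated here as the package's
own study conditions) back the statistical acceptance checks:

* `calibration_recovery_config()` — 50 studies × 2 blocks × 2 sites,
  six minimal-intensity categories, zero SNH slopes, zero inflation off,
  so the Poisson total-abundance model `group * lui` with
  study/block/site intercepts *is* the generative model and every
  coefficient has a closed-form truth
  (`calibration_recovery_truth()`). One hundred replicates give the
  nominal-95% Wald coverage.
* `calibration_null_config()` — 12 studies × 2 × 4, three categories
  with effects identical across groups (the interaction null); 500
  replicates measure how often backwards selection retains `group:lui`
  at `alpha = 0.05`.

Other numerical choices: quartiles by linear interpolation (type 7) in
the outlier rule `O > Q_3 + 1.5\,\mathrm{IQR}`, applied once to the
pooled abundance distribution; bias-corrected Chao1
(`S_obs + F_1(F_1-1)/(2(F_2+1))`), defined even without doubletons;
Moran's I with inverse great-circle-distance weights, row-standardised,
normal-approximation p-values under randomisation (binary within-radius
weights available), requiring ≥ 4 distinct locations and rejecting
degenerate inputs rather than propagating NaN; Laplace approximation for
the Poisson GLMM, with an adaptive Gauss–Hermite quadrature oracle
bounding its likelihood error on small fixtures; singular (boundary)
random-effect fits are reported as converged with a recorded message,
as they are valid optima.

The zero-inflated negative-binomial abundance re-fit used in the
original sensitivity analysis is deliberately out of scope; its place is
taken by `zero_audit()`, which reports the exact count and share of zero
abundance records and flags large shares for the analyst.

# Known limitations

* The contribution matrix transcription ships as a default, not a
  fact: users applying the pipeline to other services must edit the
  YAML and re-validate.
* `log(x+1)` percentage differences are approximate for small
  abundances (see above).
* The overall pipeline run in examples and the acceptance script uses
  desk-scale problem sizes (tens of studies, hundreds of sites); the
  same code paths scale to database-scale inputs but runtimes will be
  dominated by `glmer`.
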