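Package: pollcontrib
Title: Species-Level Crop-Pollination Contribution Groups and Land-Use Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies animal species by their contribution to crop
    pollination using an ecosystem-service contribution matrix that combines
    the importance of a species for pollination with the certainty of the
    underlying evidence. Aggregates PREDICTS-style assemblage surveys into
    per-site, per-group species richness and total abundance, computes the
    capped percentage of semi-natural habitat surrounding each site from
    categorical land-cover rasters, and fits hierarchical mixed-effects
    models of richness (Poisson, with quasi-likelihood overdispersion
    adjustment) and log-abundance (Gaussian, with habitat interactions)
    across a combined land-use/use-intensity disturbance axis, with
    backwards stepwise likelihood-ratio selection. Includes a synthetic
    survey generator with known ground truth and a sensitivity suite
    (Chao1 richness, interquartile-range outlier rule, leave-one-out by
    study, per-study Moran's I, zero-abundance audit, importance-only
    regrouping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    ape,
    geosphere,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
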