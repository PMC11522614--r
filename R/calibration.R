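#' Frozen calibration designs for the model layer
#'
#' Two fixed synthetic study designs used to check the statistical
#' machinery against its own generative model.
#'
#' `calibration_recovery_config()` is a 50-study, 2-blocks-per-study,
#' 2-sites-per-block design over the six land-use types at minimal
#' intensity, with zero SNH slopes and no zero inflation, so that the
#' Poisson total-abundance model with `group * lui` fixed effects and
#' study/block/site intercepts is exactly the generative model and every
#' coefficient has a known true value (`calibration_recovery_truth()`).
#'
#' `calibration_null_config()` is a 12-study design with three land-use
#' categories whose effects are identical across contribution groups —
#' the null under which a `group:lui` interaction should be retained by
#' backwards selection in about `alpha` of replicates.
#'
#' @param seed Integer seed for one replicate.
#' @return A [sim_config].
#' @export
calibration_recovery_config <- function(seed) {
  eff <- list("primary vegetation minimal" = c(0, 0, 0),
              "secondary vegetation minimal" = c(-0.3, -0.2, -0.1),
              "plantation forest minimal" = c(-0.5, -0.3, -0.1),
              "cropland minimal" = c(-0.8, -0.3, 0.3),
              "pasture minimal" = c(-0.7, -0.3, 0.2),
              "urban minimal" = c(-1.0, -0.4, 0.25))
  sim_config(n_studies = 50, blocks_per_study = 2, sites_per_block = 2,
             n_species = 40, lui_effects = eff,
             snh_slopes = lapply(eff, function(e) c(0, 0, 0)),
             study_sd = 0.4, block_sd = 0.3, site_sd = 0.2,
             baseline_log_abundance = 1, zero_inflation_prob = 0,
             seed = seed)
}

#' @rdname calibration_recovery_config
#' @param config The config a dataset was generated from.
#' @param dataset The generated `synthetic_dataset` (group sizes enter the
#'   intercept and group main effects).
#' @return Named vector of true coefficients under treatment coding.
#' @export
calibration_recovery_truth <- function(config, dataset) {
  eff <- config$lui_effects
  n_g <- table(factor(dataset$species$group,
                      levels = c("low", "medium", "high")))
  luis <- setdiff(names(eff), "primary vegetation minimal")
  truth <- c("(Intercept)" = config$baseline_log_abundance +
               log(unname(n_g["low"])))
  for (g in c("medium", "high"))
    truth[paste0("group", g)] <- log(n_g[[g]] / n_g[["low"]])
  for (l in luis) truth[paste0("lui", l)] <- eff[[l]][1]
  for (l in luis) for (g in c("medium", "high"))
    truth[paste0("group", g, ":lui", l)] <-
      eff[[l]][match(g, c("low", "medium", "high"))] - eff[[l]][1]
  truth
}

#' @rdname calibration_recovery_config
#' @export
calibration_null_config <- function(seed) {
  same <- c(0, -0.25, -0.5)   # identical across groups: no interaction
  eff <- list("primary vegetation minimal" = c(0, 0, 0),
              "cropland minimal" = rep(same[2], 3),
              "urban minimal" = rep(same[3], 3))
  sim_config(n_studies = 12, blocks_per_study = 2, sites_per_block = 4,
             n_species = 30, lui_effects = eff,
             snh_slopes = lapply(eff, function(e) c(0, 0, 0)),
             study_sd = 0.4, block_sd = 0.3, site_sd = 0.2,
             baseline_log_abundance = 1.5, zero_inflation_prob = 0.2,
             seed = seed)
}
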