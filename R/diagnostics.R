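#' Bias-corrected Chao1 species richness
#'
#' Corrects observed richness for incomplete sampling using singleton and
#' doubleton counts: `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, where `F1`
#' and `F2` are the numbers of species observed exactly once and exactly
#' twice. The bias-corrected form is defined even without doubletons and
#' never falls below the observed richness.
#'
#' @param counts Non-negative integer abundance vector for one assemblage
#'   (zeros are ignored).
#' @return Estimated richness (scalar).
#' @export
chao1 <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("chao1 requires non-negative integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Replace observed richness by Chao1 estimates in a metrics table
#'
#' Sensitivity variant of [site_metrics()]: per site and group, richness
#' is re-estimated with [chao1()] from the per-species counts and rounded
#' to the nearest integer so the Poisson richness model applies
#' unchanged. Occurrence-only sites keep their observed richness
#' (singleton/doubleton counts are undefined for presence data).
#'
#' @param metrics Metrics table from [site_metrics()].
#' @param assemblage The merged assemblage the metrics came from.
#' @param species Classified species table (columns `species`, `group`).
#' @return `metrics` with a `richness_obs` column preserving the input
#'   and `richness` replaced by rounded Chao1 estimates.
#' @export
chao1_metrics <- function(metrics, assemblage, species) {
  metrics$richness_obs <- metrics$richness
  grp <- species$group[match(assemblage$species_name, species$species)]
  key_a <- paste(assemblage$site_id, grp, sep = "\r")
  for (i in seq_len(nrow(metrics))) {
    if (!metrics$has_abundance[i]) next
    v <- assemblage$measurement[key_a == paste(metrics$site_id[i],
                                               metrics$group[i], sep = "\r")]
    if (length(v)) metrics$richness[i] <- round(chao1(v))
  }
  metrics
}

#' Interquartile-range outlier rule for total abundance
#'
#' Flags values strictly greater than `Q3 + 1.5 * IQR`, with quartiles by
#' linear interpolation of the empirical distribution (the default
#' quantile convention). The rule is computed once on the supplied pooled
#' values and returned for audit, so re-applying the returned threshold
#' is idempotent.
#'
#' @param x Numeric vector of total abundances (at least 4 values).
#' @return List: `values` (retained), `removed` (indices of outliers),
#'   `rule` (`q3`, `iqr`, `threshold`).
#' @export
remove_outliers <- function(x) {
  if (length(x) < 4L)
    stop("outlier rule needs at least 4 values, got ", length(x))
  q3 <- unname(stats::quantile(x, 0.75, type = 7))
  iqr <- unname(stats::IQR(x, type = 7))
  thr <- q3 + 1.5 * iqr
  out <- which(x > thr)
  list(values = if (length(out)) x[-out] else x, removed = out,
       rule = list(q3 = q3, iqr = iqr, threshold = thr))
}

#' Leave-one-out-by-study coefficient stability
#'
#' Refits the model once per held-out study and summarises, per fixed
#' effect, the range of estimates across refits and whether any refit
#' changed the sign of a coefficient that is significant (|z| > 1.96) in
#' the full fit. Refit non-convergence is recorded per study, not fatal.
#'
#' @param metrics Metrics table (column `study_id`).
#' @param spec A [model_spec].
#' @return List: `table` (per-coefficient full estimate, min, max,
#'   significant flag, sign-change flag), `estimates` (study x
#'   coefficient matrix), `nonconverged` (study ids).
#' @export
loo_by_study <- function(metrics, spec) {
  studies <- unique(metrics$study_id)
  if (length(studies) < 3L)
    stop("leave-one-out by study needs at least 3 studies, got ",
         length(studies))
  full <- fit_glmm(metrics, spec)
  est <- matrix(NA_real_, length(studies), length(full$coefficients),
                dimnames = list(studies, names(full$coefficients)))
  bad <- character(0)
  for (s in studies) {
    f <- tryCatch(fit_glmm(metrics[metrics$study_id != s, , drop = FALSE],
                           spec),
                  error = function(e) NULL)
    if (is.null(f)) { bad <- c(bad, s); next }
    if (!f$converged) bad <- c(bad, s)
    est[s, names(f$coefficients)] <- f$coefficients
  }
  z <- full$coefficients / fixef_se(full)
  tab <- data.frame(
    coefficient = names(full$coefficients),
    estimate = unname(full$coefficients),
    min = apply(est, 2L, min, na.rm = TRUE),
    max = apply(est, 2L, max, na.rm = TRUE),
    significant = unname(abs(z) > 1.96))
  tab$sign_change <- tab$significant &
    (sign(tab$min) != sign(tab$estimate) |
       sign(tab$max) != sign(tab$estimate))
  rownames(tab) <- NULL
  list(table = tab, estimates = est, nonconverged = bad)
}

#' Moran's I spatial autocorrelation of residuals
#'
#' Tests one study's residuals for spatial autocorrelation using
#' inverse great-circle-distance weights (row-standardised, zero
#' diagonal), with the p-value from the normal approximation under the
#' randomisation assumption. Binary within-radius weights are available
#' as an alternative. Requires at least 4 sites with distinct
#' coordinates; duplicated coordinates receive the largest finite
#' inverse-distance weight.
#'
#' @param residuals Numeric residual vector.
#' @param coords Matrix or `data.frame` of `longitude`, `latitude` rows
#'   matching `residuals`.
#' @param weights `"inverse_distance"` (default) or `"binary"`.
#' @param radius_m Neighbourhood radius for binary weights.
#' @param study_id Optional identifier copied to the output.
#' @return One-row `data.frame`: `study_id`, `statistic`, `expected`,
#'   `p_value`, `n_sites`.
#' @export
morans_i <- function(residuals, coords,
                     weights = c("inverse_distance", "binary"),
                     radius_m = 10000, study_id = NA_character_) {
  weights <- match.arg(weights)
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (nrow(coords) != n) stop("residuals and coordinates differ in length")
  ndist <- nrow(unique(round(coords, 9)))
  if (ndist < 4L)
    stop("Moran's I needs at least 4 distinct site locations, got ", ndist)
  d <- geosphere::distm(coords, fun = geosphere::distHaversine)
  w <- if (weights == "inverse_distance") {
    wi <- 1 / d
    diag(wi) <- 0
    if (any(!is.finite(wi))) {
      mx <- max(wi[is.finite(wi)])
      wi[!is.finite(wi)] <- mx   # coincident pairs: strongest neighbours
    }
    wi
  } else {
    (d <= radius_m) * 1
  }
  diag(w) <- 0
  w <- w / rowSums(w)
  m <- ape::Moran.I(residuals, w, scaled = FALSE,
                    alternative = "two.sided")
  data.frame(study_id = study_id, statistic = m$observed,
             expected = m$expected, p_value = m$p.value, n_sites = n)
}

#' Per-study Moran's I on model residuals
#'
#' Applies [morans_i()] to each study with at least 4 distinct site
#' locations among the fitted observations (residuals of one study may
#' span several rows per site; they are averaged per site before
#' testing). Under no spatial autocorrelation about 5% of studies are
#' expected significant at p < 0.05.
#'
#' @param fitted A `fitted_model`.
#' @param weights,radius_m Passed to [morans_i()].
#' @return List: `table` (one row per tested study), `frac_significant`
#'   (share of tested studies with p < 0.05), `n_skipped`.
#' @export
morans_i_by_study <- function(fitted, weights = "inverse_distance",
                              radius_m = 10000) {
  d <- fitted$data
  d$.resid <- stats::residuals(fitted$fit)
  skipped <- 0L
  rows <- list()
  for (s in unique(d$study_id)) {
    ds <- d[d$study_id == s, , drop = FALSE]
    agg <- stats::aggregate(cbind(longitude, latitude, .resid) ~ site_id,
                            data = ds, FUN = mean)
    if (nrow(unique(round(agg[, c("longitude", "latitude")], 9))) < 4L) {
      skipped <- skipped + 1L
      next
    }
    rows[[s]] <- morans_i(agg$.resid, agg[, c("longitude", "latitude")],
                          weights = weights, radius_m = radius_m,
                          study_id = s)
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       frac_significant = if (is.null(tab)) NA_real_
                          else mean(tab$p_value < 0.05),
       n_skipped = skipped)
}

#' Audit zero abundance records
#'
#' Counts exact zeros among abundance measurements and flags when their
#' share exceeds a reporting threshold — the summary the package offers
#' in place of a zero-inflated count model refit.
#'
#' @param abundances Numeric vector (e.g. `total_abundance` of the
#'   metrics table, or raw measurements).
#' @param report_threshold Fraction above which `flagged` is `TRUE`.
#' @return List: `n_zero`, `n`, `fraction`, `flagged`.
#' @export
zero_audit <- function(abundances, report_threshold = 0.1) {
  abundances <- abundances[!is.na(abundances)]
  n0 <- sum(abundances == 0)
  list(n_zero = n0, n = length(abundances),
       fraction = if (length(abundances)) n0 / length(abundances)
                  else NA_real_,
       flagged = length(abundances) > 0 &&
         n0 / length(abundances) > report_threshold)
}

#' Re-run a fitted pipeline with importance-only contribution groups
#'
#' Sensitivity analysis for the certainty axis: species are regrouped by
#' [importance_only_group()] (so importance is not down-weighted by
#' evidential certainty), metrics are re-aggregated, the state's selected
#' model specs are refitted, and the coefficients of both runs are
#' compared term by term.
#'
#' @param state Pipeline state from [run_pipeline()].
#' @return List: `groups_changed` (species whose group differs),
#'   `fits` (refits per model), `comparison` (per model, a `data.frame`
#'   of coefficient, estimate, estimate_importance_only, difference for
#'   the terms shared by both fits).
#' @export
rerun_importance_only <- function(state) {
  sp2 <- state$species
  sp2$group <- importance_only_group(sp2, state$matrix)
  changed <- sp2$species[sp2$group != state$species$group]
  bal <- balance_orders(sp2, state$assemblage)
  met <- site_metrics(bal$assemblage, bal$species)
  if (!is.null(state$sites_snh)) {
    i <- match(met$site_id, state$sites_snh$site_id)
    met$snh_pct <- state$sites_snh$snh_pct[i]
  }
  fits <- lapply(state$fits, function(f) fit_glmm(met, f$spec))
  comparison <- lapply(names(fits), function(nm) {
    a <- state$fits[[nm]]$coefficients
    b <- fits[[nm]]$coefficients
    shared <- intersect(names(a), names(b))
    data.frame(coefficient = shared, estimate = unname(a[shared]),
               estimate_importance_only = unname(b[shared]),
               difference = unname(b[shared] - a[shared]))
  })
  names(comparison) <- names(fits)
  list(groups_changed = changed, fits = fits, comparison = comparison)
}
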