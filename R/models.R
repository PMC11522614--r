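#' Specify a hierarchical model of assemblage metrics
#'
#' Two model families are used in the main analysis: a Poisson GLMM of
#' species richness with random intercepts for study identity, spatial
#' block and site identity (the site term absorbs extra-Poisson
#' variation), and a Gaussian LMM of log-transformed (`log(x + 1)`) total
#' abundance with study and block intercepts and surrounding-SNH
#' interactions. `response = "abundance"` fits total abundance counts
#' directly on the Poisson scale (the scale on which the synthetic
#' generator is exactly log-linear, used for parameter-recovery checks).
#'
#' @param response One of `"richness"`, `"abundance"` (Poisson) or
#'   `"log_abundance"` (Gaussian on `log(x+1)`).
#' @param fixed_terms Character vector over
#'   `group`, `lui`, `snh`, `group:lui`, `group:snh`, `lui:snh`,
#'   `group:lui:snh`; every interaction requires its marginal terms.
#' @param random_intercepts Subset of `study`, `block`, `site`; the site
#'   (observation-level) term is only allowed with the Poisson family.
#' @param reference_lui,reference_group Reference levels for treatment
#'   coding (minimally used primary vegetation; low contribution).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response = c("richness", "log_abundance", "abundance"),
                       fixed_terms = c("group", "lui", "group:lui"),
                       random_intercepts = c("study", "block", "site"),
                       reference_lui = "primary vegetation minimal",
                       reference_group = "low") {
  response <- match.arg(response)
  family <- if (response == "log_abundance") "gaussian" else "poisson"
  allowed <- c("group", "lui", "snh", "group:lui", "group:snh", "lui:snh",
               "group:lui:snh")
  bad <- setdiff(fixed_terms, allowed)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  for (t in fixed_terms) {
    need <- required_marginals(t)
    miss <- setdiff(need, fixed_terms)
    if (length(miss))
      stop("term '", t, "' requires marginal term(s): ",
           paste(miss, collapse = ", "))
  }
  bad <- setdiff(random_intercepts, c("study", "block", "site"))
  if (length(bad))
    stop("unknown random intercept(s): ", paste(bad, collapse = ", "))
  if ("site" %in% random_intercepts && family != "poisson")
    stop("the site (observation-level) random intercept is an ",
         "overdispersion device for the Poisson family only")
  structure(list(response = response, family = family,
                 fixed_terms = fixed_terms,
                 random_intercepts = random_intercepts,
                 reference_lui = reference_lui,
                 reference_group = reference_group),
            class = "model_spec")
}

# Marginal terms implied by an interaction, e.g. group:lui -> group, lui.
required_marginals <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) return(character(0))
  unlist(lapply(seq_len(length(parts) - 1L), function(k)
    utils::combn(parts, k, paste, collapse = ":")))
}

# Terms droppable under marginality: not contained in a retained
# higher-order term.
droppable_terms <- function(fixed_terms) {
  keep <- vapply(fixed_terms, function(t) {
    others <- setdiff(fixed_terms, t)
    !any(vapply(others, function(o) t %in% required_marginals(o),
                logical(1)))
  }, logical(1))
  fixed_terms[keep]
}

prepare_model_frame <- function(metrics, spec) {
  d <- as.data.frame(metrics)
  if (!nrow(d)) stop("metrics table is empty")
  d$group <- stats::relevel(factor(d$group), ref = spec$reference_group)
  lev <- unique(c(spec$reference_lui, sort(unique(d$lui))))
  d$lui <- factor(d$lui, levels = intersect(lev, unique(d$lui)))
  if (spec$response == "richness") {
    if (any(d$richness != round(d$richness)))
      stop("richness must be integer counts")
    d$.y <- d$richness
  } else {
    if (is.null(d$total_abundance)) stop("metrics lack total_abundance")
    d <- d[d$has_abundance, , drop = FALSE]
    if (spec$response == "abundance") {
      if (any(d$total_abundance != round(d$total_abundance)))
        stop("Poisson abundance model needs integer counts")
      d$.y <- d$total_abundance
    } else {
      d$.y <- log1p(d$total_abundance)
    }
  }
  snh_center <- NA_real_
  if (any(grepl("snh", spec$fixed_terms))) {
    if (is.null(d$snh_pct)) stop("spec includes snh but metrics lack snh_pct")
    snh_center <- mean(d$snh_pct / 100)   # centred on the modelled rows
    d$snh <- d$snh_pct / 100 - snh_center
  }
  for (f in c("group", "lui"))
    if (f %in% spec$fixed_terms && nlevels(droplevels(d[[f]])) < 2L)
      stop("factor '", f, "' has fewer than 2 observed levels")
  d$lui <- droplevels(d$lui)
  attr(d, "snh_center") <- snh_center
  d
}

fixed_formula_rhs <- function(fixed_terms) {
  if (!length(fixed_terms)) "1" else paste(fixed_terms, collapse = " + ")
}

random_formula_part <- function(random_intercepts) {
  map <- c(study = "(1 | study_id)", block = "(1 | block_id)",
           site = "(1 | site_id)")
  paste(map[random_intercepts], collapse = " + ")
}

#' Fit a hierarchical mixed-effects model
#'
#' Poisson models are fitted by Laplace-approximated maximum likelihood
#' (`lme4::glmer`), Gaussian models by maximum likelihood (`lme4::lmer`,
#' `REML = FALSE`, so that likelihood-ratio comparisons between fixed
#' structures are valid). With no random intercepts the fit falls back to
#' `glm`/`lm`. Treatment coding is applied against the reference levels in
#' the spec; the SNH covariate enters as a fraction centred at its sample
#' mean. A rank-deficient fixed design is rejected listing the aliased
#' columns; non-convergence is flagged on the result, not thrown.
#'
#' @param metrics Metrics `data.frame` from [site_metrics()] (plus
#'   `snh_pct` from [snh_for_sites()] when SNH terms are used).
#' @param spec A [model_spec].
#' @return A `fitted_model`: list with `coefficients`, `vcov`,
#'   `re_variances`, `loglik`, `n_obs`, `converged`, `dispersion`
#'   (1 until [overdispersion_adjust()] estimates it), `spec`, the
#'   underlying `fit`, and the centring constant `snh_center`.
#' @export
fit_glmm <- function(metrics, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_model_frame(metrics, spec)
  rhs <- fixed_formula_rhs(spec$fixed_terms)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  msgs <- character(0)
  fit <- if (length(spec$random_intercepts)) {
    fml <- stats::as.formula(paste(".y ~", rhs, "+",
                                   random_formula_part(spec$random_intercepts)))
    withCallingHandlers({
      if (spec$family == "poisson")
        lme4::glmer(fml, data = d, family = stats::poisson())
      else lme4::lmer(fml, data = d, REML = FALSE)
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    if (spec$family == "poisson") stats::glm(fml, data = d,
                                             family = stats::poisson())
    else stats::lm(fml, data = d)
  }
  mer <- inherits(fit, "merMod")
  # a boundary (singular) fit is a valid optimum, not a convergence failure
  not_singular <- function(m) !grepl("boundary \\(singular\\)", m)
  conv <- if (mer)
    !any(not_singular(unlist(fit@optinfo$conv$lme4$messages))) &&
      fit@optinfo$conv$opt == 0L && !any(not_singular(msgs))
  else TRUE
  re_var <- if (mer) {
    vc <- lme4::VarCorr(fit)
    stats::setNames(vapply(vc, function(m) m[1L, 1L], numeric(1)), names(vc))
  } else numeric(0)
  structure(list(
    coefficients = if (mer) lme4::fixef(fit) else stats::coef(fit),
    vcov = as.matrix(stats::vcov(fit)),
    re_variances = re_var,
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d), converged = conv, dispersion = 1,
    messages = msgs, spec = spec, fit = fit,
    snh_center = attr(d, "snh_center"), data = d),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model:", x$spec$family, "response =", x$spec$response,
      "| n =", x$n_obs, "| logLik =", round(x$loglik, 2),
      "| converged =", x$converged,
      "| dispersion =", round(x$dispersion, 3), "\n")
  if (length(x$re_variances)) {
    cat("random-intercept variances:\n")
    print(round(x$re_variances, 4))
  }
  cat("fixed effects:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Backwards stepwise selection by likelihood-ratio tests
#'
#' Starting from the full spec, repeatedly refits (by maximum likelihood)
#' each currently droppable term — one not contained in a retained
#' higher-order interaction — and removes the term with the largest
#' likelihood-ratio p-value above `alpha`; stops when every droppable
#' term tests below `alpha`. Ties are broken by dropping the
#' highest-order term first, then lexicographically, so the trace is a
#' deterministic function of the data and `alpha`.
#'
#' @param spec Full [model_spec].
#' @param metrics Metrics table.
#' @param alpha Retention threshold for the LRT p-value (default 0.05).
#' @return List: `spec` (selected), `fit` (fit of the selected spec),
#'   `trace` (`data.frame` of every comparison: step, term, df, chisq,
#'   p_value, dropped).
#' @export
backwards_select <- function(spec, metrics, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  current <- spec
  fit <- fit_glmm(metrics, current)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- droppable_terms(current$fixed_terms)
    if (!length(cand)) break
    ord <- order(-vapply(cand, function(t)
      length(strsplit(t, ":", fixed = TRUE)[[1L]]), integer(1)), cand)
    cand <- cand[ord]
    rows <- lapply(cand, function(t) {
      red <- current
      red$fixed_terms <- setdiff(red$fixed_terms, t)
      rfit <- fit_glmm(metrics, red)
      df <- length(fit$coefficients) - length(rfit$coefficients)
      chisq <- max(0, 2 * (fit$loglik - rfit$loglik))
      data.frame(step = step, term = t, df = df, chisq = chisq,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 dropped = FALSE)
    })
    tab <- do.call(rbind, rows)
    drop_i <- which(tab$p_value > alpha)
    if (!length(drop_i)) { trace[[step]] <- tab; break }
    # candidates are pre-ordered (higher order, then lexicographic), so
    # which.max resolves p-value ties deterministically
    best <- drop_i[which.max(tab$p_value[drop_i])]
    tab$dropped[best] <- TRUE
    trace[[step]] <- tab
    current$fixed_terms <- setdiff(current$fixed_terms, tab$term[best])
    fit <- fit_glmm(metrics, current)
  }
  list(spec = current, fit = fit,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(0), term = character(0),
                               df = integer(0), chisq = numeric(0),
                               p_value = numeric(0), dropped = logical(0)))
}

#' Quasi-likelihood overdispersion adjustment
#'
#' Estimates the dispersion ratio of a Poisson fit as the Pearson
#' chi-square statistic over the residual degrees of freedom. When the
#' ratio exceeds 1, the coefficient covariance is scaled by it (so
#' standard errors inflate by its square root); point estimates are
#' unchanged. Equidispersed fits pass through with dispersion about 1.
#'
#' @param fitted A `fitted_model` with Poisson family.
#' @return The `fitted_model` with `dispersion` set and `vcov` rescaled
#'   when dispersion > 1.
#' @export
overdispersion_adjust <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_model"))
  if (fitted$spec$family != "poisson")
    stop("overdispersion adjustment applies to Poisson fits only")
  pr <- stats::residuals(fitted$fit, type = "pearson")
  rdf <- stats::df.residual(fitted$fit)
  phi <- sum(pr^2) / rdf
  fitted$dispersion <- phi
  if (phi > 1) fitted$vcov <- fitted$vcov * phi
  fitted
}

#' Standard errors of the fixed effects
#' @param fitted A `fitted_model`.
#' @return Named numeric vector (reflects any overdispersion adjustment).
#' @export
fixef_se <- function(fitted) {
  stats::setNames(sqrt(diag(fitted$vcov)), names(fitted$coefficients))
}

model_matrix_row <- function(fitted, lui, group, snh_pct) {
  d <- fitted$data
  nd <- d[1L, , drop = FALSE]
  if (!(group %in% levels(d$group))) stop("unknown group level: ", group)
  if (!(lui %in% levels(d$lui))) stop("unknown lui level: ", lui)
  nd$group <- factor(group, levels = levels(d$group))
  nd$lui <- factor(lui, levels = levels(d$lui))
  if ("snh" %in% names(d)) {
    if (is.na(snh_pct)) stop("model includes snh: snh_pct required")
    if (snh_pct < 0 || snh_pct > 100)
      stop("snh_pct outside [0, 100]: ", snh_pct)
    nd$snh <- snh_pct / 100 - fitted$snh_center
  }
  rhs <- fixed_formula_rhs(fitted$spec$fixed_terms)
  stats::model.matrix(stats::as.formula(paste("~", rhs)), nd)[1L, ]
}

#' Percentage difference relative to the reference land use
#'
#' Computes the link-scale contrast between a (land-use category, group,
#' SNH) combination and the reference condition (by default minimally
#' used primary vegetation in the same group at the same SNH), and
#' back-transforms it to a percentage difference
#' `100 * (exp(contrast) - 1)`, with a delta-method standard error from
#' the coefficient covariance (so it reflects any overdispersion
#' adjustment). For the Gaussian log-abundance model the contrast is on
#' the `log(x+1)` scale, and the back-transform is the same exponential
#' ratio; this is exactly multiplicative in `x + 1` rather than `x`, a
#' deliberate approximation shared with the Poisson scale.
#'
#' @param fitted A `fitted_model`.
#' @param lui,group Target land-use/intensity category and contribution
#'   group (levels present in the fit).
#' @param snh_pct Surrounding-SNH percentage in `[0, 100]` (required when
#'   the model has SNH terms).
#' @param ref_lui Reference category (defaults to the spec's reference).
#' @param ref_snh_pct Reference SNH percentage (defaults to `snh_pct`).
#' @return One-row `data.frame`: `lui`, `group`, `snh_pct`, `pct_diff`,
#'   `se_pct`.
#' @export
predict_relative <- function(fitted, lui, group, snh_pct = NA_real_,
                             ref_lui = NULL, ref_snh_pct = NULL) {
  stopifnot(inherits(fitted, "fitted_model"))
  if (is.null(ref_lui)) ref_lui <- fitted$spec$reference_lui
  if (is.null(ref_snh_pct)) ref_snh_pct <- snh_pct
  x1 <- model_matrix_row(fitted, lui, group, snh_pct)
  x0 <- model_matrix_row(fitted, ref_lui, group, ref_snh_pct)
  dlt <- x1 - x0
  eta <- sum(dlt * fitted$coefficients)
  v <- as.numeric(dlt %*% fitted$vcov %*% dlt)
  data.frame(lui = lui, group = group, snh_pct = snh_pct,
             pct_diff = 100 * (exp(eta) - 1),
             se_pct = 100 * exp(eta) * sqrt(v))
}

#' Prediction table across categories, groups and SNH levels
#'
#' Builds the standard results table: every land-use/intensity category
#' and contribution group in the fit, at low and high surrounding-SNH
#' percentages (by default the 33rd and 66th percentiles of the fitted
#' data), each relative to the reference category in the same group at
#' the high SNH level.
#'
#' @param fitted A `fitted_model`.
#' @param snh_levels Numeric vector of SNH percentages; `NULL` uses the
#'   33rd/66th percentiles when the model has SNH terms, otherwise a
#'   single SNH-free contrast per category.
#' @return `data.frame` of [predict_relative()] rows.
#' @export
predict_relative_table <- function(fitted, snh_levels = NULL) {
  d <- fitted$data
  has_snh <- "snh" %in% names(d)
  if (is.null(snh_levels)) {
    snh_levels <- if (has_snh)
      unname(stats::quantile((d$snh + fitted$snh_center) * 100,
                             c(1 / 3, 2 / 3)))
    else NA_real_
  }
  ref_snh <- if (has_snh) max(snh_levels) else NA_real_
  combos <- expand.grid(lui = levels(d$lui), group = levels(d$group),
                        snh_pct = snh_levels, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    predict_relative(fitted, combos$lui[i], combos$group[i],
                     combos$snh_pct[i], ref_snh_pct = ref_snh)))
  out
}
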