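metrics_from_counts <- function(y, study, block = study, site = NULL,
                                lui = "primary vegetation minimal",
                                group = "low", snh_pct = NULL) {
  d <- data.frame(study_id = study, block_id = block,
                  site_id = if (is.null(site)) seq_along(y) else site,
                  longitude = 0, latitude = 0,
                  lui = lui, group = group,
                  richness = y, total_abundance = y, has_abundance = TRUE)
  if (!is.null(snh_pct)) d$snh_pct <- snh_pct
  d
}

test_that("model specs enforce marginality and family constraints", {
  expect_error(model_spec(fixed_terms = c("group", "group:lui")),
               "requires marginal")
  expect_error(model_spec("log_abundance",
                          random_intercepts = c("study", "site")),
               "Poisson family only")
  expect_error(model_spec(fixed_terms = "climate"), "unknown fixed term")
  s <- model_spec("log_abundance",
                  fixed_terms = c("group", "lui", "snh", "group:lui",
                                  "group:snh", "lui:snh", "group:lui:snh"),
                  random_intercepts = c("study", "block"))
  expect_identical(s$family, "gaussian")
})

test_that("gaussian intercept-only fit with no random terms is the mean", {
  m <- metrics_from_counts(c(0, 1), study = c("s1", "s2"))
  m$total_abundance <- c(0, 1)
  spec <- model_spec("log_abundance", fixed_terms = character(0),
                     random_intercepts = character(0))
  f <- fit_glmm(m, spec)
  expect_equal(unname(f$coefficients["(Intercept)"]),
               mean(log1p(c(0, 1))))
  expect_true(f$converged)
})

test_that("Laplace log-likelihood matches adaptive Gauss-Hermite quadrature", {
  set.seed(31)
  ng <- 5; nper <- 4
  study <- rep(sprintf("s%d", 1:ng), each = nper)
  b <- rnorm(ng, 0, 0.6)
  x <- rep(c(0, 1), length.out = ng * nper)
  y <- rpois(ng * nper, exp(2.2 + 0.4 * x + b[rep(1:ng, each = nper)]))
  d <- metrics_from_counts(y, study,
                           lui = rep(c("primary vegetation minimal",
                                       "cropland intense"),
                                     length.out = ng * nper))
  spec <- model_spec("richness", fixed_terms = "lui",
                     random_intercepts = "study")
  f <- quiet_fit(d, spec)
  X <- cbind(1, x)
  gh <- gh_loglik_poisson(y, X, study,
                          beta = unname(f$coefficients),
                          sigma = sqrt(unname(f$re_variances["study_id"])))
  expect_equal(f$loglik, gh, tolerance = 1e-3)
})

test_that("poisson fit with negligible RE variance matches a plain GLM", {
  set.seed(77)
  y <- rpois(120, exp(1 + 0.5 * rep(c(0, 1), 60)))
  lui <- rep(c("primary vegetation minimal", "cropland intense"), 60)
  d <- metrics_from_counts(y, study = rep(sprintf("s%d", 1:6), each = 20),
                           lui = lui)
  spec <- model_spec("richness", fixed_terms = "lui",
                     random_intercepts = "study")
  f <- quiet_fit(d, spec)
  g <- glm(y ~ factor(lui, levels = unique(lui)), family = poisson())
  expect_lt(unname(f$re_variances["study_id"]), 1e-3)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
})

test_that("rank-deficient designs are rejected naming aliased terms", {
  d <- metrics_from_counts(rpois(20, 3), study = rep(c("a", "b"), 10),
                           lui = "cropland intense", group = "low")
  d$lui[1:10] <- "primary vegetation minimal"
  d$snh_pct <- ifelse(d$lui == "cropland intense", 80, 20) # aliased with lui
  spec <- model_spec("richness", fixed_terms = c("lui", "snh"),
                     random_intercepts = "study")
  expect_error(quiet_fit(d, spec), "aliased")
})

test_that("backwards selection drops null terms and keeps real ones", {
  set.seed(90)
  n_st <- 12; nper <- 24
  study <- rep(sprintf("s%02d", 1:n_st), each = nper)
  g <- rep(rep(c("low", "medium", "high"), each = nper / 3), n_st)
  lui <- rep(rep(c("primary vegetation minimal", "cropland intense"),
                 times = nper / 2), n_st)
  b <- rnorm(n_st, 0, 0.3)[rep(1:n_st, each = nper)]
  eta <- 3 + 0.4 * (g != "low") - 0.5 * (lui != "primary vegetation minimal") +
    1.2 * (g == "high" & lui != "primary vegetation minimal") + b
  y <- round(expm1(pmax(eta + rnorm(n_st * nper, 0, 0.3), 0)))
  d <- metrics_from_counts(y, study, group = g, lui = lui)
  spec <- model_spec("log_abundance",
                     fixed_terms = c("group", "lui", "group:lui"),
                     random_intercepts = "study")
  sel <- backwards_select(spec, d)
  # strong interaction: full model returned, trace records the attempt
  expect_true("group:lui" %in% sel$spec$fixed_terms)
  expect_true(all(!sel$trace$dropped))
  # remove the interaction signal: term is dropped, mains tested next
  eta0 <- eta - 1.2 * (g == "high" & lui != "primary vegetation minimal")
  d0 <- d
  d0$total_abundance <- round(expm1(pmax(eta0 + rnorm(n_st * nper, 0, 0.3),
                                         0)))
  sel0 <- backwards_select(spec, d0)
  expect_false("group:lui" %in% sel0$spec$fixed_terms)
  expect_true(all(c("group", "lui") %in% sel0$spec$fixed_terms))
  expect_identical(sel0$trace$term[sel0$trace$dropped], "group:lui")
  # deterministic trace
  sel0b <- backwards_select(spec, d0)
  expect_identical(sel0$trace, sel0b$trace)
})

test_that("LRT statistics are non-negative along the selection trace", {
  set.seed(14)
  d <- metrics_from_counts(rpois(60, 4),
                           study = rep(sprintf("s%d", 1:6), each = 10),
                           lui = sample(c("primary vegetation minimal",
                                          "cropland intense"), 60, TRUE))
  spec <- model_spec("richness", fixed_terms = "lui",
                     random_intercepts = "study")
  sel <- backwards_select(spec, d)
  expect_true(all(sel$trace$chisq >= 0))
})

test_that("overdispersion adjustment scales the covariance by phi", {
  set.seed(55)
  mu <- exp(1.2)
  y <- rnbinom(300, mu = mu, size = mu / 2)   # variance = 3 * mean
  d <- metrics_from_counts(y, study = rep(sprintf("s%d", 1:10), each = 30))
  spec <- model_spec("richness", fixed_terms = character(0),
                     random_intercepts = "study")
  f <- quiet_fit(d, spec)
  adj <- overdispersion_adjust(f)
  expect_gt(adj$dispersion, 1.5)
  expect_equal(adj$vcov, f$vcov * adj$dispersion)
  expect_equal(fixef_se(adj), fixef_se(f) * sqrt(adj$dispersion))
  expect_equal(adj$coefficients, f$coefficients)
  # equidispersed data pass through nearly unchanged
  d2 <- metrics_from_counts(rpois(300, mu),
                            study = rep(sprintf("s%d", 1:10), each = 30))
  f2 <- overdispersion_adjust(quiet_fit(d2, spec))
  expect_equal(f2$dispersion, 1, tolerance = 0.25)
  expect_error(overdispersion_adjust(
    quiet_fit(metrics_from_counts(c(0, 1), c("a", "b")),
              model_spec("log_abundance", fixed_terms = character(0),
                         random_intercepts = character(0)))),
    "Poisson fits only")
})

test_that("relative predictions back-transform link-scale contrasts", {
  set.seed(4)
  lui <- rep(c("primary vegetation minimal", "cropland intense"), 50)
  y <- rpois(100, exp(1 + log(2) * (lui == "cropland intense")))
  d <- metrics_from_counts(y, study = rep(sprintf("s%d", 1:5), each = 20),
                           lui = lui)
  spec <- model_spec("richness", fixed_terms = "lui",
                     random_intercepts = "study")
  f <- quiet_fit(d, spec)
  pr <- predict_relative(f, "cropland intense", "low")
  eta <- unname(f$coefficients["luicropland intense"])
  expect_equal(pr$pct_diff, 100 * (exp(eta) - 1))
  expect_gt(pr$pct_diff, -100)
  # reference against itself is exactly zero with zero SE
  self <- predict_relative(f, "primary vegetation minimal", "low")
  expect_equal(self$pct_diff, 0)
  expect_equal(self$se_pct, 0)
  expect_error(predict_relative(f, "grassland", "low"), "unknown lui")
})

test_that("delta-method SE agrees with a parametric bootstrap", {
  set.seed(123)
  lui <- rep(c("primary vegetation minimal", "cropland intense"), 60)
  eta <- 1.5 + 0.6 * (lui == "cropland intense")
  y <- rpois(120, exp(eta))
  d <- metrics_from_counts(y, study = "s1", lui = lui)
  spec <- model_spec("richness", fixed_terms = "lui",
                     random_intercepts = character(0))
  f <- fit_glmm(d, spec)
  pr <- predict_relative(f, "cropland intense", "low")
  boots <- replicate(1000, {
    yb <- rpois(120, exp(as.vector(cbind(1, lui == "cropland intense") %*%
                                     f$coefficients)))
    db <- d; db$richness <- yb
    fb <- fit_glmm(db, spec)
    predict_relative(fb, "cropland intense", "low")$pct_diff
  })
  expect_equal(pr$se_pct, sd(boots), tolerance = 0.2)
})

test_that("snh enters centred and predictions respect its bounds", {
  set.seed(66)
  n <- 120
  lui <- rep(c("primary vegetation minimal", "cropland minimal"), n / 2)
  snh <- runif(n, 0, 100)
  eta <- 2 - 0.4 * (lui == "cropland minimal") + 0.8 * (snh / 100)
  d <- metrics_from_counts(round(expm1(eta)),
                           study = rep(sprintf("s%d", 1:6), each = 20),
                           lui = lui, snh_pct = snh)
  spec <- model_spec("log_abundance",
                     fixed_terms = c("group", "lui", "snh"),
                     random_intercepts = "study")
  # group has one level here: drop it from the spec
  spec$fixed_terms <- c("lui", "snh")
  f <- quiet_fit(d, spec)
  expect_equal(f$snh_center, mean(snh / 100))
  expect_error(predict_relative(f, "cropland minimal", "low",
                                snh_pct = 150), "outside \\[0, 100\\]")
  tab <- predict_relative_table(f)
  expect_equal(nrow(tab), 2 * 2)   # 2 lui x 1 group x 2 snh levels
  expect_true(all(tab$pct_diff >= -100))
})
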