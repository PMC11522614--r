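# Independent oracles used across the suite. These deliberately share no
# code with the package: plain loops and textbook formulas.

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

# Adaptive Gauss-Hermite marginal log-likelihood of a Poisson GLMM with a
# single grouping factor and random intercepts u_g ~ N(0, sigma^2):
# for each group, centre the quadrature at the conditional mode.
gh_loglik_poisson <- function(y, X, group, beta, sigma, n_nodes = 25) {
  gh <- gauss_hermite(n_nodes)
  eta0 <- as.vector(X %*% beta)
  total <- 0
  for (g in unique(group)) {
    i <- group == g
    h <- function(u)
      sum(stats::dpois(y[i], exp(eta0[i] + u), log = TRUE)) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    opt <- stats::optimize(function(u) -h(u), c(-12 * sigma - 5, 12 * sigma + 5))
    mode <- opt$minimum
    eps <- 1e-4
    hess <- (h(mode + eps) - 2 * h(mode) + h(mode - eps)) / eps^2
    s <- 1 / sqrt(-hess)
    z <- mode + sqrt(2) * s * gh$nodes
    lo <- vapply(z, h, numeric(1)) + gh$nodes^2 + log(gh$weights) +
      log(sqrt(2) * s)
    m <- max(lo)
    total <- total + m + log(sum(exp(lo - m)))
  }
  total
}

# Per-pixel brute-force SNH oracle: enumerate every raster cell (one row
# at a time), include it when its centre lies within the great-circle
# radius, weight by cos(latitude), cap the SNH contribution.
brute_snh <- function(lon, lat, raster, legend, radius_m) {
  num <- 0; den <- 0; n_in <- 0L
  clons <- raster$xmin + (seq_len(raster$ncol) - 0.5) * raster$xres
  for (i in seq_len(raster$nrow)) {
    clat <- raster$ymax - (i - 0.5) * raster$yres
    d <- geosphere::distHaversine(c(lon, lat), cbind(clons, clat))
    inside <- which(d <= radius_m)
    if (!length(inside)) next
    n_in <- n_in + length(inside)
    w <- cos(clat * pi / 180)
    for (j in inside) {
      k <- which(legend$code == raster$values[i, j])
      den <- den + w
      if (legend$snh_flag[k])
        num <- num + w * legend$max_cover_pct[k] / 100
    }
  }
  list(snh_pct = 100 * num / den, n_cells = n_in)
}

# Direct double-sum Moran's I with a given (already row-standardised)
# weight matrix.
moran_brute <- function(z, w) {
  n <- length(z)
  zc <- z - mean(z)
  s0 <- sum(w)
  (n / s0) * sum(w * outer(zc, zc)) / sum(zc^2)
}

# Canonical evidence set realising one (importance, certainty) cell,
# written out by hand (independent of the package generator).
hand_evidence <- function(species, importance, certainty) {
  deps <- c(very_high = "essential;essential;great",
            high = "great;great;modest",
            medium = "modest;modest;little",
            low = "little;little;none")[[importance]]
  genus <- strsplit(species, " ")[[1]][1]
  kind_level <- switch(certainty,
                       high = list("crop_pollinator_true", "species", species),
                       medium = list("crop_pollinator_true", "genus", genus),
                       low = list("crop_pollinator_possible", "genus", genus))
  data.frame(taxon_name = kind_level[[3]], taxonomic_level = kind_level[[2]],
             evidence_kind = kind_level[[1]], confidence_score = NA_real_,
             crop_dependences = deps)
}

quiet_fit <- function(...) suppressMessages(fit_glmm(...))
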