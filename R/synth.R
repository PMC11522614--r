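#' Configuration for the synthetic survey generator
#'
#' Collects the ground-truth parameters of the generative model:
#' hierarchical design sizes (studies > spatial blocks > sites), the
#' species pool and its split across contribution groups, log-scale
#' land-use/use-intensity effects and semi-natural-habitat slopes per
#' group, random-intercept standard deviations at study, block and site
#' level, a baseline log abundance, and a species-by-site zero-inflation
#' probability. Defaults are illustrative: a qualitative pattern in which
#' low-contribution species decline with disturbance and intensity while
#' high-contribution species respond less negatively (or positively) in
#' cropland, pasture and urban sites.
#'
#' @param n_studies,blocks_per_study,sites_per_block,n_species Design
#'   counts, all at least 1.
#' @param species_group_probs Probabilities of a species falling in the
#'   low/medium/high contribution group; must sum to 1.
#' @param lui_effects Named list mapping each land-use/intensity category
#'   (see [lui_levels()]) to a numeric 3-vector of log-scale effects
#'   (low, medium, high group). Categories absent from the list are not
#'   simulated.
#' @param snh_slopes Named list with the same shape: per-category slopes
#'   per unit SNH fraction (0-1), per group.
#' @param study_sd,block_sd,site_sd Random-intercept standard deviations
#'   (>= 0).
#' @param baseline_log_abundance Intercept of the log mean count.
#' @param zero_inflation_prob Probability that a species-by-site count is
#'   forced to zero, mimicking the excess zeros of real assemblage
#'   abundance records.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_studies = 20, blocks_per_study = 2,
                       sites_per_block = 4, n_species = 60,
                       species_group_probs = c(low = 0.6, medium = 0.25,
                                               high = 0.15),
                       lui_effects = default_lui_effects(),
                       snh_slopes = default_snh_slopes(),
                       study_sd = 0.5, block_sd = 0.3, site_sd = 0.2,
                       baseline_log_abundance = 1,
                       zero_inflation_prob = 0.2, seed = 1L) {
  cfg <- list(n_studies = n_studies, blocks_per_study = blocks_per_study,
              sites_per_block = sites_per_block, n_species = n_species,
              species_group_probs = species_group_probs,
              lui_effects = lui_effects, snh_slopes = snh_slopes,
              study_sd = study_sd, block_sd = block_sd, site_sd = site_sd,
              baseline_log_abundance = baseline_log_abundance,
              zero_inflation_prob = zero_inflation_prob,
              seed = as.integer(seed))
  for (f in c("n_studies", "blocks_per_study", "sites_per_block",
              "n_species"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1)
      stop("invalid sim_config field '", f, "': must be a count >= 1")
  for (f in c("study_sd", "block_sd", "site_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid sim_config field '", f, "': must be a non-negative sd")
  if (length(cfg$species_group_probs) != 3L ||
      abs(sum(cfg$species_group_probs) - 1) > 1e-8)
    stop("invalid sim_config field 'species_group_probs': ",
         "need 3 probabilities summing to 1")
  if (cfg$zero_inflation_prob < 0 || cfg$zero_inflation_prob > 1)
    stop("invalid sim_config field 'zero_inflation_prob': must be in [0,1]")
  bad <- setdiff(names(cfg$lui_effects), lui_levels())
  if (length(bad))
    stop("invalid sim_config field 'lui_effects': unknown categories ",
         paste(bad, collapse = ", "))
  if (!all(vapply(cfg$lui_effects, length, integer(1)) == 3L))
    stop("invalid sim_config field 'lui_effects': each entry needs 3 values")
  bad <- setdiff(names(cfg$snh_slopes), names(cfg$lui_effects))
  if (length(bad))
    stop("invalid sim_config field 'snh_slopes': categories ",
         paste(bad, collapse = ", "), " lack a matching lui_effects entry")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_lui_effects <- function() {
  base <- list("primary vegetation" = c(0, 0, 0),
               "secondary vegetation" = c(-0.3, -0.2, -0.1),
               "plantation forest" = c(-0.5, -0.3, -0.1),
               "cropland" = c(-0.8, -0.3, 0.3),
               "pasture" = c(-0.7, -0.3, 0.2),
               "urban" = c(-1.0, -0.4, 0.25))
  step <- list(minimal = c(0, 0, 0), light = c(-0.2, -0.1, 0),
               intense = c(-0.4, -0.2, 0.1))
  out <- list()
  for (lu in land_use_types)
    for (ui in use_intensities)
      out[[paste(lu, ui)]] <-
        if (lu == "primary vegetation" && ui == "minimal") c(0, 0, 0)
        else base[[lu]] + step[[ui]]
  out
}

#' @rdname sim_config
#' @export
zero_lui_effects <- function() {
  stats::setNames(rep(list(c(0, 0, 0)), 18L), lui_levels())
}

#' @rdname sim_config
#' @export
default_snh_slopes <- function() {
  out <- stats::setNames(rep(list(c(0.4, 0.1, 0)), 18L), lui_levels())
  for (ui in use_intensities)
    out[[paste("cropland", ui)]] <- c(0.6, 0.2, -0.2)
  out
}

synthetic_orders <- c("Apodiformes", "Chiroptera", "Coleoptera",
                      "Didelphimorphia", "Diptera", "Hymenoptera",
                      "Lepidoptera", "Passeriformes", "Squamata")

default_legend <- function() {
  data.frame(
    code = 1:4,
    label = c("Tree cover, broadleaved, evergreen, closed (>40%)",
              "Tree cover, needleleaved, evergreen, open (15%-40%)",
              "Cropland, rainfed", "Urban areas"))
}

# Canonical crop-dependence multiset realising each importance level
# (the strongest dependence class covers over half of the crops).
importance_deps <- c(very_high = "essential;essential;great",
                     high = "great;great;modest",
                     medium = "modest;modest;little",
                     low = "little;little;none")

# Cells a synthetic evidence set can realise: every non-negligible
# importance at every certainty, plus the no-evidence cell.
achievable_cells <- function(spec) {
  cells <- spec$cells[spec$cells$importance != spec$importance_levels[1L], ,
                      drop = FALSE]
  rbind(cells[, c("importance", "certainty", "group")],
        data.frame(importance = spec$importance_levels[1L],
                   certainty = spec$certainty_levels[1L],
                   group = cell_group(spec, spec$importance_levels[1L],
                                      spec$certainty_levels[1L])))
}

#' Generate evidence records realising target matrix cells
#'
#' For every species the generator emits a canonical evidence set whose
#' classification under `spec` is exactly the assigned (importance,
#' certainty) cell: a crop-pollinator record whose dependence profile
#' realises the importance level and whose true/possible status and
#' taxonomic resolution realise the certainty level, occasionally
#' accompanied by a strictly weaker flower-visitation record that the
#' higher-cell tie-break ignores. Species assigned the no-evidence cell
#' get no records.
#'
#' @param species Character vector of binomials.
#' @param assignment `data.frame` with columns `species`, `importance`,
#'   `certainty`; one row per species. Negligible importance is only
#'   realisable at the lowest certainty (absence of evidence carries no
#'   evidence record).
#' @param seed Integer seed.
#' @param spec A [matrix_spec].
#' @return Evidence `data.frame` as accepted by [classify_evidence()].
#' @export
simulate_evidence <- function(species, assignment, seed,
                              spec = default_matrix()) {
  assignment <- as.data.frame(assignment)
  missing <- setdiff(species, assignment$species)
  if (length(missing))
    stop("species with no target cell: ", paste(utils::head(missing, 3L),
                                                collapse = ", "))
  ach <- achievable_cells(spec)
  key <- paste(assignment$importance, assignment$certainty)
  bad <- !(key %in% paste(ach$importance, ach$certainty))
  if (any(bad))
    stop("unrealisable target cell(s): ", paste(unique(key[bad]),
                                                collapse = "; "))
  withr_seed(seed, {
    recs <- lapply(match(species, assignment$species), function(i) {
      imp <- assignment$importance[i]; cert <- assignment$certainty[i]
      sp <- assignment$species[i]
      if (imp == spec$importance_levels[1L]) return(NULL)
      lvl <- switch(cert,
        high = c("crop_pollinator_true", "species"),
        medium = if (stats::runif(1) < 0.5)
          c("crop_pollinator_true", "genus")
        else c("crop_pollinator_possible", "species"),
        low = c("crop_pollinator_possible", "genus"))
      main <- data.frame(
        taxon_name = if (lvl[2L] == "genus") genus_token(sp) else sp,
        taxonomic_level = lvl[2L], evidence_kind = lvl[1L],
        confidence_score = NA_real_,
        crop_dependences = importance_deps[[imp]])
      if (stats::runif(1) < 0.3)   # strictly dominated extra evidence
        main <- rbind(main, data.frame(
          taxon_name = genus_token(sp), taxonomic_level = "genus",
          evidence_kind = "flower_visitation_only", confidence_score = 1,
          crop_dependences = NA_character_))
      main
    })
    ev <- do.call(rbind, recs)
    if (is.null(ev))
      ev <- data.frame(taxon_name = character(0),
                       taxonomic_level = character(0),
                       evidence_kind = character(0),
                       confidence_score = numeric(0),
                       crop_dependences = character(0))
    ev$record_id <- if (nrow(ev)) paste0("ev", seq_len(nrow(ev)))
                    else character(0)
    rownames(ev) <- NULL
    ev
  })
}

#' Simulate a hierarchical assemblage survey with known ground truth
#'
#' Generates a PREDICTS-like dataset: studies laid out on disjoint
#' geographic tiles, blocks as disjoint strips within each tile, sites
#' uniform within blocks; a categorical land-cover raster over the whole
#' domain from which each site's surrounding-SNH percentage is computed
#' (1-km radius) with the same machinery the analysis pipeline uses;
#' per-species site counts drawn as Poisson with log mean
#' `baseline + lui_effect(group) + snh_slope(group) * snh_fraction +
#' study + block + site` random intercepts, then zeroed with the
#' configured zero-inflation probability; and an evidence table whose
#' classification reproduces each species' assigned matrix cell.
#' Richness and total abundance are internally consistent because both
#' derive from the same per-species counts. The assemblage table lists,
#' for every site, all species recorded anywhere in the same study
#' (including zero counts), mirroring how a study's sampled universe
#' defines in-scope zeros.
#'
#' @param config A [sim_config].
#' @param spec Contribution matrix used for the evidence round trip.
#' @return A `synthetic_dataset` list: `assemblage` (long table),
#'   `species` (name, order, group, target cell), `evidence`, `raster`,
#'   `legend`, `sites` (per-site design incl. `snh_pct` and random
#'   intercepts), `latent` (per species x site expected count and
#'   zero-inflation flag), `truth` (the config).
#' @export
simulate_surveys <- function(config, spec = default_matrix()) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  withr_seed(config$seed, {
    ns <- config$n_studies; nb <- config$blocks_per_study
    npb <- config$sites_per_block
    tile <- 0.25
    gx <- ceiling(sqrt(ns))
    margin <- 0.02

    studies <- data.frame(study_id = sprintf("S%03d", seq_len(ns)))
    studies$col <- (seq_len(ns) - 1L) %% gx
    studies$row <- (seq_len(ns) - 1L) %/% gx
    site_rows <- list()
    for (s in seq_len(ns)) {
      x0 <- studies$col[s] * tile; y0 <- studies$row[s] * tile
      bw <- tile / nb
      for (b in seq_len(nb)) {
        bx0 <- x0 + (b - 1L) * bw
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          source_id = sprintf("R%03d", s), study_id = studies$study_id[s],
          block_id = sprintf("%s_B%d", studies$study_id[s], b),
          site_id = sprintf("%s_B%d_P%02d", studies$study_id[s], b,
                            seq_len(npb)),
          longitude = stats::runif(npb, bx0 + margin, bx0 + bw - margin),
          latitude = stats::runif(npb, y0 + margin, y0 + tile - margin))
      }
    }
    sites <- do.call(rbind, site_rows)
    luis <- names(config$lui_effects)
    sites$lui <- sample(luis, nrow(sites), replace = TRUE)
    lu_ui <- do.call(rbind, strsplit(sites$lui, " (?=[a-z]+$)", perl = TRUE))
    sites$land_use <- lu_ui[, 1L]
    sites$use_intensity <- lu_ui[, 2L]

    ext <- c(-0.06, gx * tile + 0.06,
             -0.06, ceiling(ns / gx) * tile + 0.06)
    lc <- simulate_landcover(ext, resolution = 0.003,
                             legend = default_legend(),
                             seed = config$seed + 1L)
    sites <- snh_for_sites(sites, lc$raster, lc$legend, radius_m = 1000)
    stopifnot(!anyNA(sites$snh_pct))
    snh_frac <- sites$snh_pct / 100

    # random intercepts
    b_study <- stats::setNames(stats::rnorm(ns, 0, config$study_sd),
                               studies$study_id)
    blocks <- unique(sites$block_id)
    b_block <- stats::setNames(stats::rnorm(length(blocks), 0,
                                            config$block_sd), blocks)
    b_site <- stats::setNames(stats::rnorm(nrow(sites), 0, config$site_sd),
                              sites$site_id)
    sites$re_study <- b_study[sites$study_id]
    sites$re_block <- b_block[sites$block_id]
    sites$re_site <- b_site[sites$site_id]

    # species pool: one genus per species so genus-level evidence is 1-1
    nsp <- config$n_species
    species <- data.frame(
      species = sprintf("Genus%04d species%04d", seq_len(nsp), seq_len(nsp)),
      order = sample(synthetic_orders, nsp, replace = TRUE))
    groups <- c("low", "medium", "high")
    species$group <- sample(groups, nsp, replace = TRUE,
                            prob = config$species_group_probs)
    ach <- achievable_cells(spec)
    species$importance <- NA_character_
    species$certainty <- NA_character_
    for (i in seq_len(nsp)) {
      cand <- ach[ach$group == species$group[i], , drop = FALSE]
      j <- sample(nrow(cand), 1L)
      species$importance[i] <- cand$importance[j]
      species$certainty[i] <- cand$certainty[j]
    }

    gidx <- match(species$group, groups)
    eff <- vapply(seq_len(nrow(sites)), function(k)
      config$lui_effects[[sites$lui[k]]], numeric(3))       # 3 x nsites
    slp <- vapply(seq_len(nrow(sites)), function(k) {
      s <- config$snh_slopes[[sites$lui[k]]]
      if (is.null(s)) c(0, 0, 0) else s
    }, numeric(3))
    # nsp x nsites log-mean
    eta <- config$baseline_log_abundance +
      eff[gidx, , drop = FALSE] +
      slp[gidx, , drop = FALSE] * rep(snh_frac, each = nsp) +
      rep(sites$re_study + sites$re_block + sites$re_site, each = nsp)
    mu <- exp(eta)
    counts <- matrix(stats::rpois(length(mu), mu), nrow = nsp)
    zeroed <- matrix(stats::runif(length(mu)) < config$zero_inflation_prob,
                     nrow = nsp)
    counts[zeroed] <- 0L

    # long assemblage table: a study's universe is every species recorded
    # at least once within it
    rows <- list()
    for (s in studies$study_id) {
      sidx <- which(sites$study_id == s)
      universe <- which(rowSums(counts[, sidx, drop = FALSE]) > 0)
      if (!length(universe)) next
      rows[[s]] <- data.frame(
        source_id = rep(sites$source_id[sidx], each = length(universe)),
        study_id = s,
        block_id = rep(sites$block_id[sidx], each = length(universe)),
        site_id = rep(sites$site_id[sidx], each = length(universe)),
        longitude = rep(sites$longitude[sidx], each = length(universe)),
        latitude = rep(sites$latitude[sidx], each = length(universe)),
        land_use = rep(sites$land_use[sidx], each = length(universe)),
        use_intensity = rep(sites$use_intensity[sidx],
                            each = length(universe)),
        sampling_method = "standard_transect",
        sampling_dates = paste0("2005-", s),
        species_name = rep(species$species[universe], times = length(sidx)),
        order = rep(species$order[universe], times = length(sidx)),
        measurement = as.numeric(counts[universe, sidx]),
        is_abundance = TRUE)
    }
    assemblage <- do.call(rbind, rows)
    rownames(assemblage) <- NULL

    latent <- data.frame(
      site_id = rep(sites$site_id, each = nsp),
      species_name = rep(species$species, times = nrow(sites)),
      mu = as.numeric(mu), zeroed = as.logical(zeroed))

    evidence <- simulate_evidence(
      species$species,
      species[, c("species", "importance", "certainty")],
      seed = config$seed + 2L, spec = spec)

    structure(list(assemblage = assemblage, species = species,
                   evidence = evidence, raster = lc$raster,
                   legend = lc$legend, sites = sites, latent = latent,
                   truth = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", x$truth$n_studies, "studies,",
      nrow(x$sites), "sites,", nrow(x$species), "species (",
      paste(table(x$species$group)[c("low", "medium", "high")],
            collapse = "/"), "low/med/high ),",
      nrow(x$assemblage), "assemblage rows\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `assemblage.csv`, `species.csv`, `evidence.csv`, `legend.csv`
#' and `landcover.asc` under `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$assemblage, file.path(dir, "assemblage.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$evidence, file.path(dir, "evidence.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$legend),
                   file.path(dir, "legend.csv"), row.names = FALSE)
  write_asc(dataset$raster, file.path(dir, "landcover.asc"))
  invisible(dir)
}
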