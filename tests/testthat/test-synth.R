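make_null_config <- function(seed = 1, ...) {
  sim_config(n_studies = 4, blocks_per_study = 2, sites_per_block = 3,
             n_species = 15, lui_effects = zero_lui_effects(),
             snh_slopes = lapply(zero_lui_effects(), function(e) e),
             study_sd = 0, block_sd = 0, site_sd = 0,
             baseline_log_abundance = 0, zero_inflation_prob = 0,
             seed = seed, ...)
}

test_that("config validation names the offending field", {
  expect_error(sim_config(n_studies = 0), "'n_studies'")
  expect_error(sim_config(study_sd = -1), "'study_sd'")
  expect_error(sim_config(species_group_probs = c(0.5, 0.5, 0.5)),
               "'species_group_probs'")
  expect_error(sim_config(zero_inflation_prob = 1.5),
               "'zero_inflation_prob'")
  expect_error(sim_config(lui_effects = list(savannah = c(0, 0, 0))),
               "unknown categories")
})

test_that("null generative model has unit expected counts everywhere", {
  ds <- simulate_surveys(make_null_config())
  expect_true(all(abs(ds$latent$mu - 1) < 1e-12))
  # counts are Poisson(1) draws: mean near 1 over the latent table
  expect_gt(mean(ds$assemblage$measurement), 0.7)
  expect_lt(mean(ds$assemblage$measurement), 1.35)
})

test_that("identical configs give byte-identical datasets", {
  a <- simulate_surveys(sim_config(n_studies = 4, n_species = 12, seed = 99))
  b <- simulate_surveys(sim_config(n_studies = 4, n_species = 12, seed = 99))
  expect_identical(a$assemblage, b$assemblage)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$raster$values, b$raster$values)
  c <- simulate_surveys(sim_config(n_studies = 4, n_species = 12, seed = 100))
  expect_false(identical(a$assemblage, c$assemblage))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(runif(1))
  invisible(simulate_surveys(make_null_config(seed = 77)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("study-level variance is recovered from a 200-study design", {
  cfg <- sim_config(n_studies = 200, blocks_per_study = 1,
                    sites_per_block = 2, n_species = 30,
                    lui_effects = zero_lui_effects(),
                    snh_slopes = zero_lui_effects(),
                    study_sd = 1, block_sd = 0, site_sd = 0,
                    baseline_log_abundance = 3, zero_inflation_prob = 0,
                    seed = 2024)
  ds <- simulate_surveys(cfg)
  study_mean <- tapply(log1p(ds$assemblage$measurement),
                       ds$assemblage$study_id, mean)
  expect_equal(sd(study_mean), 1, tolerance = 0.15)
})

test_that("richness and abundance are internally consistent", {
  ds <- simulate_surveys(sim_config(n_studies = 4, n_species = 20, seed = 3))
  met <- site_metrics(ds$assemblage,
                      ds$species[, c("species", "order", "group")])
  one <- ds$assemblage[ds$assemblage$site_id == met$site_id[1], ]
  grp <- ds$species$group[match(one$species_name, ds$species$species)]
  g <- met$group[1]
  expect_equal(met$richness[1],
               length(unique(one$species_name[grp == g &
                                                one$measurement > 0])))
  expect_equal(met$total_abundance[1], sum(one$measurement[grp == g]))
})

test_that("sites fall inside the raster and SNH comes from it", {
  ds <- simulate_surveys(sim_config(n_studies = 6, n_species = 10, seed = 8))
  r <- ds$raster
  expect_true(all(ds$sites$longitude > r$xmin & ds$sites$longitude < r$xmax))
  expect_true(all(ds$sites$latitude > r$ymin & ds$sites$latitude < r$ymax))
  k <- which.max(ds$sites$snh_pct)
  redo <- snh_percentage(c(ds$sites$longitude[k], ds$sites$latitude[k]),
                         r, ds$legend, 1000)
  expect_equal(redo$snh_pct, ds$sites$snh_pct[k])
})

test_that("a high-importance high-certainty target yields a species-level
           true-pollinator record dominated by great dependence", {
  ev <- simulate_evidence("Peponapis pruinosa",
                          data.frame(species = "Peponapis pruinosa",
                                     importance = "high",
                                     certainty = "high"),
                          seed = 11)
  main <- ev[ev$evidence_kind == "crop_pollinator_true", ]
  expect_equal(nrow(main), 1L)
  expect_identical(main$taxonomic_level, "species")
  deps <- strsplit(main$crop_dependences, ";")[[1]]
  expect_gt(mean(deps %in% c("great", "essential")), 0.5)
})

test_that("simulated evidence classifies back to its assigned cell", {
  ds <- simulate_surveys(sim_config(n_studies = 4, n_species = 60, seed = 21))
  cls <- classify_evidence(ds$evidence, ds$species$species)
  i <- match(ds$species$species, cls$species)
  expect_identical(cls$importance[i], ds$species$importance)
  expect_identical(cls$certainty[i], ds$species$certainty)
  expect_identical(cls$group[i], ds$species$group)
  # no-evidence targets emit no records (genera are species-unique here)
  neg <- ds$species$species[ds$species$importance == "negligible"]
  expect_false(any(neg %in% ds$evidence$taxon_name))
  expect_false(any(sub(" .*", "", neg) %in% ds$evidence$taxon_name))
  expect_error(simulate_evidence("Apis mellifera",
                                 data.frame(species = "Bombus terrestris",
                                            importance = "high",
                                            certainty = "high"),
                                 seed = 1),
               "no target cell")
})

test_that("synthetic datasets round-trip through their CSV/ASC files", {
  ds <- simulate_surveys(make_null_config(seed = 12))
  dir <- withr::local_tempdir()
  write_synthetic(ds, dir)
  asm <- read.csv(file.path(dir, "assemblage.csv"))
  expect_equal(nrow(asm), nrow(ds$assemblage))
  expect_equal(read_asc(file.path(dir, "landcover.asc"))$values,
               ds$raster$values)
})
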