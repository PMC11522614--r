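test_that("the LUI axis is the 6 x 3 cross product with 18 categories", {
  grid <- expand.grid(lu = land_use_types, ui = use_intensities,
                      stringsAsFactors = FALSE)
  labels <- combine_lui(grid$lu, grid$ui)
  expect_length(unique(labels), 18L)
  expect_true("cropland intense" %in% labels)
  expect_identical(lui_levels()[1], "primary vegetation minimal")
  expect_error(combine_lui("meadow", "minimal"), "unknown land_use")
  expect_error(combine_lui("cropland", "extreme"), "unknown use_intensity")
})

test_that("inclusion filters drop incomplete binomials and unlocated sites", {
  tab <- toy_assemblage()
  tab <- rbind(tab, tab[1, ], tab[1, ], tab[1, ])
  tab$species_name[6] <- "Apis sp."
  tab$species_name[7] <- "Bombus cf. terrestris"
  tab$latitude[8] <- NA
  out <- filter_records(tab)
  expect_equal(nrow(out$data), 5L)
  expect_equal(nrow(out$log), 3L)
  expect_setequal(out$log$reason,
                  c("incomplete or uncertain binomial",
                    "missing coordinates"))
  # empty table passes through
  empty <- filter_records(tab[0, ])
  expect_equal(nrow(empty$data), 0L)
  expect_equal(nrow(empty$log), 0L)
})

test_that("filtering applies the row-by-row criteria on a mixed table", {
  tab <- do.call(rbind, replicate(10, toy_assemblage()[3, ],
                                  simplify = FALSE))
  tab$site_id <- paste0("P", 1:10)
  tab$species_name[2] <- "Apis"            # genus only
  tab$longitude[5] <- NA                   # unlocated
  tab$use_intensity[9] <- "unknown"        # outside vocabulary
  out <- filter_records(tab)
  keep_oracle <- setdiff(1:10, c(2, 5, 9))
  expect_identical(out$data$site_id, paste0("P", keep_oracle))
})

test_that("merge combines key-identical sites, summing abundances", {
  tab <- toy_assemblage()
  dup <- tab[3, ]
  dup$site_id <- "P2bis"
  dup$measurement <- 7
  merged <- merge_sites(rbind(tab, dup))
  expect_equal(length(unique(merged$site_id)), 4L)
  expect_equal(merged$measurement[merged$site_id == "P2"], 12)
  # no duplicates: identity, and hence filter->merge idempotence
  again <- merge_sites(merged)
  expect_equal(again[order(again$site_id, again$species_name), ],
               merged[order(merged$site_id, merged$species_name), ],
               ignore_attr = TRUE)
  # total abundance conserved
  expect_equal(sum(merged$measurement), sum(tab$measurement) + 7)
})

test_that("merge ORs occurrences and rejects mixed measurement kinds", {
  tab <- toy_assemblage()
  tab$is_abundance <- FALSE
  tab$measurement <- c(1, 0, 1, 0, 1)
  dup <- tab[3, ]; dup$site_id <- "X"; dup$measurement <- 0
  merged <- merge_sites(rbind(tab, dup))
  expect_equal(merged$measurement[merged$site_id == "P2"], 1)
  mix <- rbind(tab, transform(tab[3, ], is_abundance = TRUE))
  expect_error(merge_sites(mix), "mixing abundance and occurrence")
})

test_that("order balancing keeps exactly the orders spanning all groups", {
  sp <- data.frame(
    species = paste("Genus", 1:10),
    order = rep(c("Hymenoptera", "Diptera", "Coleoptera", "Araneae",
                  "Gastropoda"), each = 2),
    group = c("low", "high", "medium", "low", "high", "medium",
              "low", "low", "low", "low"))
  # brute-force oracle: tally groups per order
  tally <- tapply(sp$group, sp$order, function(g)
    all(c("low", "medium", "high") %in% g))
  asm <- data.frame(species_name = sp$species, site_id = "P1")
  # Hymenoptera lacks medium; make it balanced via a third species
  sp <- rbind(sp, data.frame(species = "Genus 11", order = "Hymenoptera",
                             group = "medium"))
  tally <- tapply(sp$group, sp$order, function(g)
    all(c("low", "medium", "high") %in% g))
  bal <- balance_orders(sp, asm)
  expect_setequal(bal$orders_retained, names(tally)[tally])
  expect_setequal(bal$species$species, sp$species[sp$order %in%
                                                    names(tally)[tally]])
  expect_true(all(bal$assemblage$species_name %in% bal$species$species))
  expect_error(balance_orders(transform(sp, order = NA), asm),
               "lacking order annotation")
})

test_that("site metrics aggregate richness and abundance per group", {
  tab <- toy_assemblage()
  met <- site_metrics(merge_sites(tab), toy_species())
  p1 <- met[met$site_id == "P1", ]
  expect_equal(p1$richness[p1$group == "high"], 1L)
  expect_equal(p1$total_abundance[p1$group == "high"], 2)
  expect_equal(p1$total_abundance[p1$group == "medium"], 3.5)
  # P1 sampled no Passeriformes species, but the study did: in-scope zero
  expect_equal(p1$richness[p1$group == "low"], 0L)
  expect_equal(p1$total_abundance[p1$group == "low"], 0)
  expect_identical(p1$lui[1], "cropland intense")
  expect_error(site_metrics(transform(tab, measurement = -1),
                            toy_species()),
               "negative measurement")
})

test_that("site metrics match a per-group sum/count oracle on random data", {
  set.seed(101)
  sp <- data.frame(species = sprintf("Genus%02d sp%02d", 1:20, 1:20),
                   order = "Diptera",
                   group = sample(c("low", "medium", "high"), 20,
                                  replace = TRUE))
  tab <- toy_assemblage()[rep(3, 20), ]
  tab$species_name <- sp$species
  tab$measurement <- rpois(20, 2)
  met <- site_metrics(tab, sp)
  for (g in unique(sp$group)) {
    i <- sp$group == g
    expect_equal(met$richness[met$group == g],
                 sum(tab$measurement[i] > 0))
    expect_equal(met$total_abundance[met$group == g],
                 sum(tab$measurement[i]))
  }
})

test_that("occurrence-only sites keep richness but carry no abundance", {
  tab <- toy_assemblage()
  tab$is_abundance <- FALSE
  tab$measurement <- as.numeric(tab$measurement > 0)
  met <- site_metrics(tab, toy_species())
  expect_true(all(!met$has_abundance))
  expect_true(all(is.na(met$total_abundance)))
  expect_equal(met$richness[met$site_id == "P1" & met$group == "high"], 1L)
})
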