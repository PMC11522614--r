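# Shared fixtures: built in code, small, deterministic.

toy_assemblage <- function() {
  data.frame(
    source_id = "R001", study_id = "S001",
    block_id = c("B1", "B1", "B1", "B2", "B2"),
    site_id = c("P1", "P1", "P2", "P3", "P4"),
    longitude = c(0.1, 0.1, 0.2, 0.3, 0.4),
    latitude = c(0.1, 0.1, 0.2, 0.3, 0.4),
    land_use = c("cropland", "cropland", "primary vegetation",
                 "pasture", "urban"),
    use_intensity = c("intense", "intense", "minimal", "light", "minimal"),
    species_name = c("Apis mellifera", "Bombus terrestris",
                     "Apis mellifera", "Apis mellifera", "Turdus merula"),
    measurement = c(2, 3.5, 5, 1, 4),
    is_abundance = TRUE,
    sampling_method = "net", sampling_dates = "2005-06")
}

toy_species <- function() {
  data.frame(species = c("Apis mellifera", "Bombus terrestris",
                         "Turdus merula"),
             order = c("Hymenoptera", "Hymenoptera", "Passeriformes"),
             group = c("high", "medium", "low"))
}

# A uniform single-category legend/raster pair around the origin.
uniform_raster <- function(code = 1L, n = 40, res = 0.003) {
  lc_raster(matrix(code, n, n), -n / 2 * res, n / 2 * res,
            -n / 2 * res, n / 2 * res)
}

snh_legend <- function() {
  classify_legend(data.frame(
    code = 1:3,
    label = c("Tree cover, broadleaved, evergreen, closed (>40%)",
              "Tree cover, needleleaved, evergreen, open (15%-40%)",
              "Urban areas")))
}

# Frozen calibration designs live in the package (R/calibration.R); the
# suite uses them under short aliases.
recovery_config <- calibration_recovery_config
recovery_truth <- calibration_recovery_truth
null_selection_config <- calibration_null_config
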