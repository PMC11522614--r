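#' Closed vocabularies for the disturbance axis
#'
#' Six land-use types crossed with three use intensities give the single
#' 18-category land-use/use-intensity axis used by all models; minimally
#' used primary vegetation is the reference category.
#' @export
land_use_types <- c("primary vegetation", "secondary vegetation",
                    "plantation forest", "cropland", "pasture", "urban")

#' @rdname land_use_types
#' @export
use_intensities <- c("minimal", "light", "intense")

#' @rdname land_use_types
#' @return `lui_levels()` returns the 18 category labels in model order
#'   (reference category first).
#' @export
lui_levels <- function() {
  as.vector(t(outer(land_use_types, use_intensities, paste)))
}

#' Combine land-use type and use intensity into one disturbance category
#'
#' @param land_use,use_intensity Character vectors (recycled) drawn from
#'   [land_use_types] and [use_intensities].
#' @return Character vector of `"<land use> <intensity>"` labels; the image
#'   over the full cross product has exactly 18 distinct values.
#' @export
combine_lui <- function(land_use, use_intensity) {
  bad <- setdiff(unique(land_use), land_use_types)
  if (length(bad)) stop("unknown land_use value(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(use_intensity), use_intensities)
  if (length(bad)) stop("unknown use_intensity value(s): ",
                        paste(bad, collapse = ", "))
  paste(land_use, use_intensity)
}

assemblage_cols <- c("source_id", "study_id", "block_id", "site_id",
                     "longitude", "latitude", "land_use", "use_intensity",
                     "species_name", "measurement", "is_abundance")

check_assemblage <- function(x, context = "assemblage table") {
  miss <- setdiff(assemblage_cols, names(x))
  if (length(miss))
    stop(context, " lacks column(s): ", paste(miss, collapse = ", "))
  invisible(x)
}

# A binomial is usable when it has a genus and a specific epithet and
# neither token signals uncertainty or an undetermined epithet.
complete_binomial <- function(name) {
  name <- trimws(ifelse(is.na(name), "", name))
  toks <- strsplit(name, "\\s+")
  placeholder <- c("sp", "sp.", "spp", "spp.", "indet", "indet.",
                   "cf", "cf.", "aff", "aff.", "gen", "gen.")
  vapply(toks, function(t) {
    if (length(t) < 2L) return(FALSE)
    if (any(grepl("\\?", t))) return(FALSE)
    !any(tolower(t) %in% placeholder)
  }, logical(1))
}

#' Apply the study inclusion filters
#'
#' Keeps only records whose species binomial is recorded, certain and
#' complete, from sites that have geographic coordinates and a land-use
#' type and use-intensity classification from the closed vocabularies.
#' Every removed row is logged with the first criterion it failed.
#'
#' @param raw Assemblage `data.frame` in long format (one row per site x
#'   species) with at least the columns `source_id`, `study_id`,
#'   `block_id`, `site_id`, `longitude`, `latitude`, `land_use`,
#'   `use_intensity`, `species_name`, `measurement`, `is_abundance`.
#' @return List with `data` (retained rows) and `log` (`data.frame` of
#'   `row`, `site_id`, `species_name`, `reason`).
#' @export
filter_records <- function(raw) {
  raw <- as.data.frame(raw)
  check_assemblage(raw, "raw table")
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  ok_name <- complete_binomial(raw$species_name)
  reason[!ok_name] <- "incomplete or uncertain binomial"
  no_coord <- is.na(raw$longitude) | is.na(raw$latitude)
  reason[is.na(reason) & no_coord] <- "missing coordinates"
  bad_lui <- !(raw$land_use %in% land_use_types) |
    !(raw$use_intensity %in% use_intensities)
  reason[is.na(reason) & bad_lui] <- "missing or unrecognised land-use/intensity"
  drop <- !is.na(reason)
  list(data = raw[!drop, , drop = FALSE],
       log = data.frame(row = which(drop),
                        site_id = raw$site_id[drop],
                        species_name = raw$species_name[drop],
                        reason = reason[drop]))
}

#' Merge duplicate sites
#'
#' Sites from the same study that share coordinates (after normalisation
#' to 6 decimal places), sampling method, sampling dates, land-use type
#' and use intensity are combined into one site: species abundances are
#' summed, occurrences OR-ed. Mixing abundance and occurrence rows within
#' one merge group is rejected. The site count never increases.
#'
#' @param tab Filtered assemblage `data.frame`; columns `sampling_method`
#'   and `sampling_dates` default to a single value when absent.
#' @return Merged assemblage `data.frame` (one row per merged site x
#'   species).
#' @export
merge_sites <- function(tab) {
  tab <- as.data.frame(tab)
  check_assemblage(tab, "filtered table")
  if (nrow(tab) == 0L) return(tab)
  if (is.null(tab$sampling_method)) tab$sampling_method <- "unspecified"
  if (is.null(tab$sampling_dates)) tab$sampling_dates <- "unspecified"
  key <- paste(tab$study_id, sprintf("%.6f", tab$longitude),
               sprintf("%.6f", tab$latitude), tab$sampling_method,
               tab$sampling_dates, tab$land_use, tab$use_intensity,
               sep = "\r")
  kinds <- tapply(tab$is_abundance, key, function(v) length(unique(v)))
  if (any(kinds > 1L))
    stop("merge group mixing abundance and occurrence measurements: ",
         gsub("\r", " / ", names(kinds)[kinds > 1L][1L]))
  # canonical site id per merge group: the first site id encountered
  first_site <- tapply(tab$site_id, key, `[`, 1L)
  tab$.site <- unname(first_site[key])
  agg_key <- paste(key, tab$species_name, sep = "\r")
  # per-group aggregation honouring each group's measurement kind
  meas <- tapply(seq_len(nrow(tab)), agg_key, function(i)
    if (tab$is_abundance[i[1L]]) sum(tab$measurement[i])
    else as.numeric(any(tab$measurement[i] > 0)))
  firsts <- tab[!duplicated(agg_key), , drop = FALSE]
  firsts$measurement <- unname(meas[paste(key, tab$species_name,
                                          sep = "\r")[!duplicated(agg_key)]])
  firsts$site_id <- firsts$.site
  firsts$.site <- NULL
  rownames(firsts) <- NULL
  firsts
}

#' Drop orders not represented in every contribution group
#'
#' Comparing groups within taxonomic orders requires each retained order
#' to contribute species to all contribution groups; orders whose species
#' fall into only some groups are removed, together with their species'
#' assemblage rows.
#'
#' @param species `data.frame` with columns `species`, `order`, `group`.
#' @param assemblage Assemblage `data.frame` whose `species_name` rows are
#'   pruned in step.
#' @param groups Required groups (default low/medium/high).
#' @return List: `orders_retained`, `species` (pruned), `assemblage`
#'   (pruned).
#' @export
balance_orders <- function(species, assemblage,
                           groups = c("low", "medium", "high")) {
  species <- as.data.frame(species)
  if (anyNA(species$order) || is.null(species$order))
    stop("species lacking order annotation: ",
         paste(utils::head(species$species[is.na(species$order)], 3L),
               collapse = ", "))
  cover <- tapply(species$group, species$order,
                  function(g) all(groups %in% g))
  keep_orders <- names(cover)[cover]
  sp_keep <- species$order %in% keep_orders
  list(orders_retained = sort(keep_orders),
       species = species[sp_keep, , drop = FALSE],
       assemblage = assemblage[assemblage$species_name %in%
                                 species$species[sp_keep], , drop = FALSE])
}

#' Per-site, per-group richness and total abundance
#'
#' Aggregates a merged assemblage table to one record per site and
#' contribution group: richness is the number of uniquely named species of
#' the group recorded with a positive measurement, total abundance the sum
#' of their (relative) abundances. A zero-richness record is emitted for a
#' (site, group) pair only when the site's study sampled at least one
#' taxon from an order containing species of that group, so absences
#' outside a study's taxonomic scope are not treated as zeros. Sites whose
#' measurements are occurrences get `has_abundance = FALSE` and an `NA`
#' total abundance.
#'
#' @param assemblage Merged assemblage `data.frame`.
#' @param species Classified species `data.frame` (columns `species`,
#'   `order`, `group`); every measured species must appear.
#' @return `data.frame` with one row per site x in-scope group:
#'   hierarchy keys, coordinates, `lui`, `group`, `richness`,
#'   `total_abundance`, `has_abundance`.
#' @export
site_metrics <- function(assemblage, species) {
  assemblage <- as.data.frame(assemblage)
  check_assemblage(assemblage)
  if (any(assemblage$measurement < 0, na.rm = TRUE))
    stop("negative measurement in assemblage table")
  unk <- setdiff(unique(assemblage$species_name), species$species)
  if (length(unk))
    stop("measured species without contribution group: ",
         paste(utils::head(unk, 3L), collapse = ", "))
  i <- match(assemblage$species_name, species$species)
  assemblage$group <- species$group[i]
  assemblage$order <- species$order[i]
  groups <- sort(unique(species$group))
  orders_of_group <- lapply(stats::setNames(groups, groups), function(g)
    unique(species$order[species$group == g]))

  sites <- assemblage[!duplicated(assemblage$site_id),
                      c("source_id", "study_id", "block_id", "site_id",
                        "longitude", "latitude", "land_use", "use_intensity")]
  sites$lui <- combine_lui(sites$land_use, sites$use_intensity)
  study_orders <- tapply(assemblage$order, assemblage$study_id, unique)

  out <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    rows <- assemblage[assemblage$site_id == s$site_id, , drop = FALSE]
    has_ab <- all(rows$is_abundance)
    in_scope <- vapply(groups, function(g)
      any(orders_of_group[[g]] %in% study_orders[[as.character(s$study_id)]]),
      logical(1))
    g_here <- groups[in_scope]
    if (!length(g_here)) return(NULL)
    do.call(rbind, lapply(g_here, function(g) {
      r <- rows[rows$group == g, , drop = FALSE]
      cbind(s, data.frame(
        group = g,
        richness = length(unique(r$species_name[r$measurement > 0])),
        total_abundance = if (has_ab) sum(r$measurement) else NA_real_,
        has_abundance = has_ab))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
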