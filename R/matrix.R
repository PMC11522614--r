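#' Load a species-level ecosystem service contribution matrix
#'
#' The contribution matrix crosses an ordered importance axis (how much a
#' species matters for crop pollination, driven by the dependence of the
#' crops it pollinates on animal-mediated pollination) with an ordered
#' certainty axis (the strength and taxonomic resolution of the evidence),
#' and maps every cell to a low/medium/high contribution group. The
#' package ships a default transcription for crop pollination
#' (`system.file("extdata", "contribution_matrix.yaml", package =
#' "pollcontrib")`), but the whole pipeline is parameterised over the
#' matrix so it can be re-used for other ecosystem services.
#'
#' Validation requires: both axes declared, a complete cell map over their
#' cross product, group labels drawn from `groups`, and contribution
#' non-decreasing along the importance axis at fixed certainty. Violations
#' are rejected naming the offending cell.
#'
#' @param path Path to a YAML file with fields `importance_levels`,
#'   `certainty_levels`, `groups` and `cells` (list of
#'   `{importance, certainty, group, rule}` entries).
#' @return A `matrix_spec` object.
#' @export
load_matrix <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("importance_levels", "certainty_levels", "cells"))
    if (is.null(cfg[[f]])) stop("matrix config lacks field '", f, "'")
  cells <- do.call(rbind, lapply(cfg$cells, function(c.)
    data.frame(importance = c.$importance, certainty = c.$certainty,
               group = c.$group,
               rule = if (is.null(c.$rule)) NA_character_ else c.$rule)))
  matrix_spec(importance_levels = unlist(cfg$importance_levels),
              certainty_levels = unlist(cfg$certainty_levels),
              groups = if (is.null(cfg$groups)) c("low", "medium", "high")
                       else unlist(cfg$groups),
              cells = cells)
}

#' @rdname load_matrix
#' @param importance_levels,certainty_levels Ordered character vectors,
#'   weakest level first.
#' @param groups Ordered contribution groups, lowest first (default
#'   low/medium/high).
#' @param cells `data.frame` with columns `importance`, `certainty`,
#'   `group` and optionally `rule`.
#' @export
matrix_spec <- function(importance_levels, certainty_levels,
                        groups = c("low", "medium", "high"), cells) {
  cells <- as.data.frame(cells)
  grid <- expand.grid(importance = importance_levels,
                      certainty = certainty_levels,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$importance, d$certainty, sep = "\r")
  missing <- setdiff(key(grid), key(cells))
  if (length(missing)) {
    m <- strsplit(missing[1L], "\r", fixed = TRUE)[[1L]]
    stop("cell map incomplete: no entry for (", m[1L], ", ", m[2L], ")")
  }
  extra <- setdiff(key(cells), key(grid))
  if (length(extra) || anyDuplicated(key(cells)))
    stop("cell map has duplicate or off-grid entries")
  if (!all(cells$group %in% groups))
    stop("cell group(s) outside declared groups: ",
         paste(setdiff(cells$group, groups), collapse = ", "))
  # contribution must not decrease as importance rises at fixed certainty
  gnum <- match(cells$group, groups)
  inum <- match(cells$importance, importance_levels)
  for (ct in certainty_levels) {
    i <- cells$certainty == ct
    o <- order(inum[i])
    g <- gnum[i][o]
    if (any(diff(g) < 0)) {
      bad <- which(diff(g) < 0)[1L] + 1L
      stop("monotonicity violation at cell (",
           cells$importance[i][o][bad], ", ", ct,
           "): group drops along the importance axis")
    }
  }
  structure(list(importance_levels = importance_levels,
                 certainty_levels = certainty_levels,
                 groups = groups, cells = cells),
            class = "matrix_spec")
}

#' Default pollination contribution matrix shipped with the package
#' @return A `matrix_spec`.
#' @export
default_matrix <- function() {
  load_matrix(system.file("extdata", "contribution_matrix.yaml",
                          package = "pollcontrib", mustWork = TRUE))
}

#' @export
print.matrix_spec <- function(x, ...) {
  cat("Ecosystem service contribution matrix:",
      length(x$importance_levels), "importance x",
      length(x$certainty_levels), "certainty levels ->",
      paste(x$groups, collapse = "/"), "contribution groups\n")
  m <- matrix(NA_character_, length(x$importance_levels),
              length(x$certainty_levels),
              dimnames = list(x$importance_levels, x$certainty_levels))
  m[cbind(x$cells$importance, x$cells$certainty)] <- x$cells$group
  print(m, quote = FALSE)
  invisible(x)
}

# Group of one (importance, certainty) cell.
cell_group <- function(spec, importance, certainty) {
  i <- spec$cells$importance == importance & spec$cells$certainty == certainty
  spec$cells$group[i][1L]
}

genus_token <- function(binomial) vapply(strsplit(binomial, "\\s+"),
                                         `[`, character(1), 1L)

# ---- evidence -> cell rules ------------------------------------------------

evidence_kinds <- c("pollination_confirmed", "pollen_transport",
                    "flower_visitation_only", "crop_pollinator_true",
                    "crop_pollinator_possible", "none")
crop_dependence_levels <- c("essential", "great", "modest", "little", "none")

# Importance implied by a crop record's dependence profile: the level is
# set by the strongest dependence class covering over half of the crops.
crop_importance <- function(deps) {
  deps <- deps[nzchar(deps)]
  n <- length(deps)
  if (n == 0L) return("low")
  f_e <- mean(deps == "essential")
  f_eg <- mean(deps %in% c("essential", "great"))
  f_egm <- mean(deps %in% c("essential", "great", "modest"))
  if (f_e > 0.5) "very_high"
  else if (f_eg > 0.5) "high"
  else if (f_egm > 0.5) "medium"
  else "low"
}

# Certainty of a crop record: true pollinator status and species-level
# resolution each raise certainty one step above the genus-level floor.
crop_certainty <- function(kind, level) {
  if (kind == "crop_pollinator_true") {
    if (level == "species") "high" else "medium"
  } else {
    if (level == "species") "medium" else "low"
  }
}

# Certainty implied by the four-level confidence score attached to
# pollinator-list records: 4 (experimental confirmation) -> high,
# 2-3 -> medium, 1 (visitation only) -> low.
score_certainty <- function(score) {
  if (is.na(score)) return("low")
  if (score >= 4) "high" else if (score >= 2) "medium" else "low"
}

# Candidate (importance, certainty) cell for a single evidence record,
# or NULL for records that carry no pollination signal.
evidence_cell <- function(kind, level, score, deps) {
  if (kind == "none") return(NULL)
  if (kind %in% c("crop_pollinator_true", "crop_pollinator_possible")) {
    list(importance = crop_importance(deps),
         certainty = crop_certainty(kind, level))
  } else {
    imp <- switch(kind, pollination_confirmed = "medium",
                  pollen_transport = "low", flower_visitation_only = "low")
    list(importance = imp, certainty = score_certainty(score))
  }
}

parse_deps <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "[;,]")[[1L]])
}

#' Classify one species' evidence into a contribution matrix cell
#'
#' Each evidence record proposes one candidate cell: crop-pollinator
#' records derive importance from the record's crop-dependence profile
#' (the strongest dependence class covering over half of the crops) and
#' certainty from true-vs-possible pollinator status and taxonomic
#' resolution; pollinator-list records derive importance from the evidence
#' kind (confirmed pollination outranks pollen transport and flower
#' visitation) and certainty from the four-level confidence score. When
#' several cells are admissible the species receives the cell whose
#' contribution group is highest (ties broken towards higher importance,
#' then higher certainty), so adding evidence can never lower a species'
#' group. A species with no (or only `none`-kind) evidence is classified
#' at negligible importance and the lowest certainty, never rejected.
#'
#' @param records `data.frame` of evidence for one species: columns
#'   `taxon_name`, `taxonomic_level` (`"species"`/`"genus"`),
#'   `evidence_kind`, `confidence_score` (1-4 or `NA`),
#'   `crop_dependences` (`;`-separated multiset over
#'   essential/great/modest/little/none, or `NA`), optional `record_id`.
#' @param spec A [matrix_spec].
#' @param species Binomial of the species being classified; may be omitted
#'   when every record is species-level for a single taxon.
#' @return One-row `data.frame`: `species`, `importance`, `certainty`,
#'   `group`, `provenance` (`;`-joined ids of the records attaining the
#'   chosen cell).
#' @export
classify_species <- function(records, spec = default_matrix(), species = NULL) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    bad <- setdiff(records$evidence_kind, evidence_kinds)
    if (length(bad)) stop("unknown evidence_kind: ", paste(bad, collapse = ", "))
    sp_names <- unique(records$taxon_name[records$taxonomic_level == "species"])
    if (length(sp_names) > 1L)
      stop("conflicting species names in record set: ",
           paste(sp_names, collapse = ", "))
    if (is.null(species))
      species <- if (length(sp_names)) sp_names else
        paste(records$taxon_name[1L], "sp.")
    g_names <- unique(records$taxon_name[records$taxonomic_level == "genus"])
    if (length(g_names) && any(g_names != genus_token(species)))
      stop("genus-level record(s) for ", paste(setdiff(g_names,
           genus_token(species)), collapse = ", "),
           " do not match species ", species)
  } else if (is.null(species)) species <- NA_character_
  if (is.null(records$record_id))
    records$record_id <- if (nrow(records)) paste0("r", seq_len(nrow(records)))
                         else character(0)
  if (is.null(records$confidence_score))
    records$confidence_score <- rep(NA_real_, nrow(records))
  if (is.null(records$crop_dependences))
    records$crop_dependences <- rep(NA_character_, nrow(records))

  cand <- lapply(seq_len(nrow(records)), function(i)
    evidence_cell(records$evidence_kind[i], records$taxonomic_level[i],
                  records$confidence_score[i],
                  parse_deps(records$crop_dependences[i])))
  keep <- !vapply(cand, is.null, logical(1))
  if (!any(keep)) {
    imp <- spec$importance_levels[1L]
    cert <- spec$certainty_levels[1L]
    return(data.frame(species = species, importance = imp, certainty = cert,
                      group = cell_group(spec, imp, cert), provenance = ""))
  }
  cand <- cand[keep]
  ids <- records$record_id[keep]
  gscore <- vapply(cand, function(c.)
    match(cell_group(spec, c.$importance, c.$certainty), spec$groups),
    integer(1))
  iscore <- vapply(cand, function(c.) match(c.$importance,
                                            spec$importance_levels), integer(1))
  cscore <- vapply(cand, function(c.) match(c.$certainty,
                                            spec$certainty_levels), integer(1))
  o <- order(gscore, iscore, cscore, decreasing = TRUE)
  best <- cand[[o[1L]]]
  att <- gscore == gscore[o[1L]] & iscore == iscore[o[1L]] &
    cscore == cscore[o[1L]]
  data.frame(species = species, importance = best$importance,
             certainty = best$certainty,
             group = cell_group(spec, best$importance, best$certainty),
             provenance = paste(ids[att], collapse = ";"))
}

#' Classify a species pool against an evidence table
#'
#' Species-level records attach by exact binomial match; genus-level
#' records propagate to every species whose genus token matches, so a
#' genus listed as pollinating marks all its species as pollinators.
#' Every species receives exactly one classification (species without
#' evidence fall to the no-evidence cell), so the groups partition the
#' pool.
#'
#' @param evidence Evidence `data.frame` (columns as in
#'   [classify_species()]).
#' @param species Character vector of binomials to classify.
#' @param spec A [matrix_spec].
#' @return `data.frame` with one row per species.
#' @export
classify_evidence <- function(evidence, species, spec = default_matrix()) {
  evidence <- as.data.frame(evidence)
  if (is.null(evidence$record_id))
    evidence$record_id <- paste0("r", seq_len(nrow(evidence)))
  species <- unique(species)
  gt <- genus_token(species)
  out <- lapply(seq_along(species), function(k) {
    sel <- (evidence$taxonomic_level == "species" &
              evidence$taxon_name == species[k]) |
           (evidence$taxonomic_level == "genus" &
              evidence$taxon_name == gt[k])
    classify_species(evidence[sel, , drop = FALSE], spec,
                     species = species[k])
  })
  do.call(rbind, out)
}

#' Contribution group from importance alone
#'
#' Sensitivity regrouping that ignores the certainty a species was actually
#' assigned: every species is read off the highest-certainty row of the
#' matrix for its importance level, so importance is not down-weighted by
#' evidential uncertainty.
#'
#' @param classification Output of [classify_species()] /
#'   [classify_evidence()] (uses the `importance` column).
#' @param spec A [matrix_spec].
#' @return Character vector of contribution groups, one per row.
#' @export
importance_only_group <- function(classification, spec = default_matrix()) {
  top <- spec$certainty_levels[length(spec$certainty_levels)]
  vapply(classification$importance,
         function(im) cell_group(spec, im, top), character(1),
         USE.NAMES = FALSE)
}
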