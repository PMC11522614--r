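#' Build and validate a land-cover legend
#'
#' A legend maps integer category codes to a semi-natural-habitat (SNH)
#' membership flag and a maximum-cover cap. SNH comprises forest,
#' grassland, wetland and shrubland; agriculture, urban, bare, water, snow
#' and ice are excluded. Many global land-cover products qualify category
#' labels with a cover range (e.g. "open (15%-40%)"): the upper bound of
#' that range caps how much of a cell the category can actually occupy, and
#' the cap weights the category's contribution to surrounding-SNH
#' percentages. Closed categories (e.g. "(>40%)") and unqualified labels
#' cap at 100.
#'
#' Missing `snh_flag` / `max_cover_pct` columns are derived from the label:
#' the flag by keyword match against the four SNH classes, the cap from the
#' parenthesised cover range. A label matching both an SNH class and an
#' excluded class (e.g. a cropland/tree mosaic) is ambiguous and rejected,
#' listing the candidate classes, so that mosaic handling is always an
#' explicit choice of the legend author.
#'
#' @param legend `data.frame` with columns `code`, `label`, and optionally
#'   `snh_flag` (logical) and `max_cover_pct` in (0, 100].
#' @return The legend with `snh_flag` and `max_cover_pct` filled in,
#'   class `lc_legend`.
#' @export
classify_legend <- function(legend) {
  legend <- as.data.frame(legend)
  req <- c("code", "label")
  miss <- setdiff(req, names(legend))
  if (length(miss)) stop("legend lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(legend$code)) stop("legend codes must be unique")
  snh_classes <- c(
    forest    = "tree cover|forest",
    grassland = "grass",
    wetland   = "wetland|flooded",
    shrubland = "shrub")
  excl <- "crop|agricult|urban|bare|sparse|water|snow|ice|lichen|moss"
  lab <- tolower(legend$label)
  if (is.null(legend$snh_flag) || anyNA(legend$snh_flag)) {
    hits <- sapply(snh_classes, function(p) grepl(p, lab))
    hits <- matrix(hits, nrow = nrow(legend))
    is_ex <- grepl(excl, lab)
    derived <- rowSums(hits) > 0 & !is_ex
    amb <- rowSums(hits) > 0 & is_ex
    if (any(amb)) {
      i <- which(amb)[1L]
      cand <- names(snh_classes)[hits[i, ]]
      stop("ambiguous legend label '", legend$label[i],
           "': matches SNH class(es) ", paste(cand, collapse = "/"),
           " and an excluded class; set snh_flag explicitly")
    }
    if (is.null(legend$snh_flag)) legend$snh_flag <- derived
    else legend$snh_flag[is.na(legend$snh_flag)] <- derived[is.na(legend$snh_flag)]
  }
  if (is.null(legend$max_cover_pct) || anyNA(legend$max_cover_pct)) {
    caps <- parse_cover_cap(legend$label)
    if (is.null(legend$max_cover_pct)) legend$max_cover_pct <- caps
    else legend$max_cover_pct[is.na(legend$max_cover_pct)] <-
        caps[is.na(legend$max_cover_pct)]
  }
  bad <- which(!(legend$max_cover_pct > 0 & legend$max_cover_pct <= 100))
  if (length(bad))
    stop("max_cover_pct outside (0,100] for code(s): ",
         paste(legend$code[bad], collapse = ", "))
  legend$snh_flag <- as.logical(legend$snh_flag)
  class(legend) <- c("lc_legend", "data.frame")
  legend
}

# Upper bound of a parenthesised cover range, e.g. "(15%-40%)" -> 40;
# open-ended "(>40%)" and unqualified labels -> 100.
parse_cover_cap <- function(labels) {
  vapply(labels, function(l) {
    m <- regmatches(l, regexec("\\(\\s*[0-9]+\\s*%?\\s*[-–]\\s*([0-9]+)\\s*%\\s*\\)", l))[[1L]]
    if (length(m) == 2L) return(as.numeric(m[2L]))
    if (grepl("\\(\\s*>\\s*[0-9]+\\s*%\\s*\\)", l)) return(100)
    m2 <- regmatches(l, regexec("\\(\\s*<\\s*([0-9]+)\\s*%\\s*\\)", l))[[1L]]
    if (length(m2) == 2L) return(as.numeric(m2[2L]))
    100
  }, numeric(1), USE.NAMES = FALSE)
}

#' Percentage of semi-natural habitat around a site
#'
#' Sums, over all raster cells whose centre lies within `radius_m` metres
#' (great-circle) of the site, the cap-weighted SNH contribution of each
#' cell, divided by the total in-disc landscape area. Cells are weighted by
#' their geodesic area (proportional to the cosine of the cell-centre
#' latitude on a regular degree grid). A cell of an SNH category with cap
#' `c` contributes at most `c`% of its area, so a disc filled with an
#' "open (15%-40%)" forest category yields 40%, and one filled with a
#' closed forest category yields 100%.
#'
#' @param site Numeric `c(lon, lat)` in decimal degrees (WGS84).
#' @param raster An [lc_raster].
#' @param legend Legend accepted by [classify_legend()], covering every
#'   code inside the disc.
#' @param radius_m Buffer radius in metres (1 km in the main analysis;
#'   10 km and 50 km as sensitivity radii).
#' @param site_id Optional identifier copied to the output.
#' @param cap_denominator If `TRUE`, the landscape denominator is also
#'   down-weighted by the caps (so the result is SNH as a share of maximum
#'   attainable cover rather than of land area). Default `FALSE`: caps
#'   apply to the SNH numerator only.
#' @return One-row `data.frame`: `site_id`, `radius_m`, `snh_pct`,
#'   `n_cells`.
#' @export
snh_percentage <- function(site, raster, legend, radius_m,
                           site_id = NA_character_, cap_denominator = FALSE) {
  stopifnot(inherits(raster, "lc_raster"))
  legend <- classify_legend(legend)
  lon <- site[[1L]]; lat <- site[[2L]]
  # the disc's bounding box must lie inside the raster extent
  dlat <- radius_m / 110574
  dlon <- radius_m / (111320 * max(cos(lat * pi / 180), 1e-9))
  if (lon - dlon < raster$xmin || lon + dlon > raster$xmax ||
      lat - dlat < raster$ymin || lat + dlat > raster$ymax)
    stop("site (", lon, ", ", lat, ") with radius ", radius_m,
         " m falls outside the raster extent")
  cc <- cell_centers(raster)
  ci <- which(cc$lon >= lon - dlon - raster$xres & cc$lon <= lon + dlon + raster$xres)
  ri <- which(cc$lat >= lat - dlat - raster$yres & cc$lat <= lat + dlat + raster$yres)
  grid <- expand.grid(row = ri, col = ci)
  d <- geosphere::distHaversine(cbind(lon, lat),
                                cbind(cc$lon[grid$col], cc$lat[grid$row]))
  inside <- d <= radius_m
  if (!any(inside))
    stop("no raster cell centre within ", radius_m, " m of site (",
         lon, ", ", lat, "); raster too coarse for this radius")
  grid <- grid[inside, , drop = FALSE]
  codes <- raster$values[cbind(grid$row, grid$col)]
  unknown <- setdiff(unique(codes), legend$code)
  if (length(unknown))
    stop("raster code(s) missing from legend: ", paste(unknown, collapse = ", "))
  li <- match(codes, legend$code)
  w <- cos(cc$lat[grid$row] * pi / 180)   # relative geodesic cell area
  num <- sum(w * as.numeric(legend$snh_flag[li]) * legend$max_cover_pct[li] / 100)
  den <- if (cap_denominator) sum(w * legend$max_cover_pct[li] / 100) else sum(w)
  data.frame(site_id = site_id, radius_m = radius_m,
             snh_pct = 100 * num / den, n_cells = nrow(grid))
}

#' Attach surrounding-SNH percentages to a site table
#'
#' Batch wrapper over [snh_percentage()]: one disc per distinct site.
#' Per-site failures (outside extent, unknown codes) are collected and
#' reported; they leave that site's `snh_pct` as `NA` rather than aborting
#' the whole batch.
#'
#' @param sites `data.frame` with columns `site_id`, `longitude`,
#'   `latitude` (extra columns pass through).
#' @param raster,legend,radius_m,cap_denominator As in [snh_percentage()].
#' @return `sites` with columns `snh_pct` and `snh_n_cells` appended, and
#'   an attribute `"snh_failures"` (`data.frame` of `site_id`, `message`,
#'   zero rows when all succeed).
#' @export
snh_for_sites <- function(sites, raster, legend, radius_m,
                          cap_denominator = FALSE) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0L) {
    sites$snh_pct <- numeric(0)
    sites$snh_n_cells <- integer(0)
    attr(sites, "snh_failures") <- data.frame(site_id = character(0),
                                              message = character(0))
    return(sites)
  }
  legend <- classify_legend(legend)
  uniq <- !duplicated(sites$site_id)
  res <- vector("list", sum(uniq))
  fail <- list()
  ids <- sites$site_id[uniq]
  lons <- sites$longitude[uniq]; lats <- sites$latitude[uniq]
  for (k in seq_along(ids)) {
    out <- tryCatch(
      snh_percentage(c(lons[k], lats[k]), raster, legend, radius_m,
                     site_id = ids[k], cap_denominator = cap_denominator),
      error = function(e) e)
    if (inherits(out, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(site_id = ids[k],
                                              message = conditionMessage(out))
      out <- data.frame(site_id = ids[k], radius_m = radius_m,
                        snh_pct = NA_real_, n_cells = NA_integer_)
    }
    res[[k]] <- out
  }
  res <- do.call(rbind, res)
  i <- match(sites$site_id, res$site_id)
  sites$snh_pct <- res$snh_pct[i]
  sites$snh_n_cells <- res$n_cells[i]
  attr(sites, "snh_failures") <-
    if (length(fail)) do.call(rbind, fail)
    else data.frame(site_id = character(0), message = character(0))
  sites
}
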