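#' Lightweight categorical land-cover raster
#'
#' An in-memory single-band categorical raster on a regular
#' longitude/latitude grid (WGS84). Values are integer category codes that
#' are interpreted through a [land-cover legend][classify_legend]. The first
#' row of `values` is the northernmost row, matching the row order of the
#' ESRI ASCII grid interchange format used by [write_asc()] / [read_asc()].
#'
#' @param values Integer matrix of category codes; rows run north to south,
#'   columns west to east.
#' @param xmin,xmax,ymin,ymax Extent in decimal degrees (cell edges, not
#'   centres).
#' @return An object of class `lc_raster`.
#' @seealso [simulate_landcover()], [snh_percentage()]
#' @export
lc_raster <- function(values, xmin, xmax, ymin, ymax) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(values != round(values), na.rm = TRUE))
    stop("raster values must be integer category codes")
  if (xmax <= xmin || ymax <= ymin)
    stop("invalid extent: need xmin < xmax and ymin < ymax")
  storage.mode(values) <- "integer"
  structure(
    list(values = values, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         nrow = nrow(values), ncol = ncol(values),
         xres = (xmax - xmin) / ncol(values),
         yres = (ymax - ymin) / nrow(values)),
    class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  cat("lc_raster:", x$nrow, "x", x$ncol, "cells,",
      "extent [", x$xmin, ",", x$xmax, "] x [", x$ymin, ",", x$ymax, "],",
      "codes:", paste(sort(unique(as.vector(x$values))), collapse = " "), "\n")
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r An `lc_raster`.
#' @return List with `lon` (length ncol, west to east) and `lat`
#'   (length nrow, north to south) cell-centre coordinates.
#' @keywords internal
cell_centers <- function(r) {
  list(lon = r$xmin + (seq_len(r$ncol) - 0.5) * r$xres,
       lat = r$ymax - (seq_len(r$nrow) - 0.5) * r$yres)
}

#' Write / read a categorical raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced interchange: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by one whitespace-separated row of codes per raster row, northernmost
#' first. Requires square cells.
#'
#' @param r An `lc_raster` with equal x and y resolution.
#' @param path Output file path.
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns an
#'   `lc_raster`.
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "lc_raster"))
  if (abs(r$xres - r$yres) > 1e-12 * max(r$xres, r$yres))
    stop("ASCII grid requires square cells (xres == yres)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", r$ncol),
    paste("nrows", r$nrow),
    paste("xllcorner", format(r$xmin, digits = 15)),
    paste("yllcorner", format(r$ymin, digits = 15)),
    paste("cellsize", format(r$xres, digits = 15)),
    "NODATA_value -9999"), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(vals) <- NULL
  if (nrow(vals) != h[["nrows"]] || ncol(vals) != h[["ncols"]])
    stop("ASCII grid dimensions do not match header")
  lc_raster(vals,
            xmin = h[["xllcorner"]],
            xmax = h[["xllcorner"]] + h[["ncols"]] * h[["cellsize"]],
            ymin = h[["yllcorner"]],
            ymax = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]])
}

#' Simulate a categorical land-cover raster
#'
#' Draws a categorical raster over a rectangular extent, either i.i.d.
#' multinomial per cell (`pattern = "random"`), a uniform single category,
#' or an alternating checkerboard of the first two legend codes (used for
#' hand-computable area-weighting fixtures).
#'
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param resolution Cell size in degrees (square cells).
#' @param legend A legend `data.frame` as accepted by [classify_legend()];
#'   every simulated code is drawn from `legend$code`. Caps must lie in
#'   (0, 100].
#' @param seed Integer seed; category frequencies are reproducible from it.
#' @param pattern One of `"random"`, `"uniform"`, `"checkerboard"`.
#' @param probs Optional per-category probabilities for `"random"`
#'   (recycled/normalised); defaults to equal weights.
#' @return List with elements `raster` (`lc_raster`) and `legend`
#'   (validated legend, see [classify_legend()]).
#' @export
simulate_landcover <- function(extent, resolution, legend, seed,
                               pattern = c("random", "uniform", "checkerboard"),
                               probs = NULL) {
  pattern <- match.arg(pattern)
  legend <- classify_legend(legend)
  codes <- legend$code
  nc <- max(1L, round((extent[2] - extent[1]) / resolution))
  nr <- max(1L, round((extent[4] - extent[3]) / resolution))
  vals <- withr_seed(seed, {
    switch(pattern,
      random = {
        p <- if (is.null(probs)) rep(1, length(codes)) else rep_len(probs, length(codes))
        matrix(sample(codes, nr * nc, replace = TRUE, prob = p / sum(p)), nr, nc)
      },
      uniform = matrix(codes[1L], nr, nc),
      checkerboard = {
        if (length(codes) < 2L) stop("checkerboard needs at least two legend codes")
        idx <- (outer(seq_len(nr), seq_len(nc), `+`) %% 2L) + 1L
        matrix(codes[idx], nr, nc)
      })
  })
  r <- lc_raster(vals, extent[1], extent[1] + nc * resolution,
                 extent[4] - nr * resolution, extent[4])
  # extent is honoured from the top-left corner; rounding keeps cells square
  list(raster = r, legend = legend)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
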