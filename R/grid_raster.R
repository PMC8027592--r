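#' Construct a regular-grid raster
#'
#' A `grid_raster` is a georeferenced 2D numeric field on a regular cell
#' grid in planar metre coordinates: the package's container for the DEM
#' (m), monthly snow depth (cm), binary canopy cover, feeding-site distance
#' (m) and relative probability-of-use surfaces.
#'
#' Conventions: `values[row, col]` with row 1 at the *bottom* (southern)
#' edge; the centre of cell `(row, col)` is at
#' `x_origin + (col - 0.5) * cell_size`, `y_origin + (row - 0.5) * cell_size`.
#'
#' @param values numeric matrix (`nrow x ncol`).
#' @param x_origin,y_origin coordinates of the lower-left grid corner (m).
#' @param cell_size cell edge length (m), strictly positive.
#' @param nodata sentinel value; cells equal to it are treated as missing.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, x_origin = 0, y_origin = 0, cell_size = 100,
                        nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("raster must have at least one cell")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(values = values, x_origin = x_origin, y_origin = y_origin,
         cell_size = cell_size, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- finite_values(x)
  cat(sprintf("grid_raster: %d x %d cells of %g m (origin %g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$x_origin, x$y_origin))
  if (length(v)) {
    cat(sprintf("  values: min %g, median %g, max %g (%d finite cells)\n",
                min(v), stats::median(v), max(v), length(v)))
  } else cat("  values: none finite\n")
  invisible(x)
}

is_grid_raster <- function(x) inherits(x, "grid_raster")

#' Finite (non-missing) cell values of a raster
#' @param r a `grid_raster`.
#' @return numeric vector of finite, non-nodata cell values.
#' @export
finite_values <- function(r) {
  v <- r$values
  v[is.finite(v) & v != r$nodata]
}

#' Test whether two rasters share the same grid
#'
#' All cross-raster operations require alignment: identical origin, cell
#' size and shape.
#'
#' @param a,b `grid_raster` objects.
#' @return logical scalar.
#' @export
rasters_aligned <- function(a, b) {
  isTRUE(all.equal(a$x_origin, b$x_origin)) &&
    isTRUE(all.equal(a$y_origin, b$y_origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values)
}

stopifnot_aligned <- function(...) {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!rasters_aligned(rs[[1]], rs[[i]]))
      stop("rasters are not aligned (origin, cell size and shape must match)")
  }
  invisible(TRUE)
}

#' Cell indices containing planar points
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates (m).
#' @return integer matrix with columns `row`, `col` (1-based).
#' @export
cell_index_at <- function(r, x, y) {
  col <- floor((x - r$x_origin) / r$cell_size) + 1L
  row <- floor((y - r$y_origin) / r$cell_size) + 1L
  outside <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  if (any(outside)) {
    i <- which(outside)[1]
    stop(sprintf("point (%g, %g) falls outside the raster extent", x[i], y[i]))
  }
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read raster values at planar points
#'
#' Values are read at the containing cell (no interpolation).
#'
#' @inheritParams cell_index_at
#' @return numeric vector of cell values.
#' @export
extract_at <- function(r, x, y) {
  idx <- cell_index_at(r, x, y)
  v <- r$values[idx]
  bad <- !is.finite(v) | v == r$nodata
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) falls on a nodata cell", x[i], y[i]))
  }
  v
}

#' Coordinates of all cell centres
#' @param r a `grid_raster`.
#' @return list with numeric vectors `x` (length ncol) and `y` (length nrow).
#' @export
cell_centers <- function(r) {
  list(
    x = r$x_origin + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
    y = r$y_origin + (seq_len(nrow(r$values)) - 0.5) * r$cell_size
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange; nodata cells are written as
#' the `nodata` sentinel. Rows are stored north-to-south as the format
#' requires.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$x_origin),
    sprintf("yllcorner %.10g", r$y_origin),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  for (row in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[row, ], trim = TRUE, digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return a `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop(sprintf("missing ASCII grid header field '%s'", k))
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body does not match declared dimensions")
  v <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # stored north-to-south
  v[v == nodata] <- NA_real_
  grid_raster(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}
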