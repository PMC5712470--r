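#' Define a regular prediction grid
#'
#' A `grid_spec` describes a regular planar grid in metres with a lower-left
#' origin. Cell `(i, j)` (0-based row `i`, column `j`) has its centre at
#' `(x_min + (j + 0.5) * cell_size, y_min + (i + 0.5) * cell_size)`; row 0 is
#' the southernmost row. This is the internal convention throughout the
#' package; the ESRI ASCII writer flips rows so that files are north-up.
#'
#' @param x_min,y_min coordinates of the lower-left corner of the grid, in
#'   metres.
#' @param n_cols,n_rows number of columns (x direction) and rows (y
#'   direction); each at least 1.
#' @param cell_size side length of the square cells, in metres (> 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, n_cols = 20, n_rows = 10, cell_size = 5)
#' head(cell_centers(g))
#' @export
grid_spec <- function(x_min, y_min, n_cols, n_rows, cell_size) {
  stopifnot(is.numeric(x_min), is.numeric(y_min), length(x_min) == 1L,
            length(y_min) == 1L, is.finite(x_min), is.finite(y_min))
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || n_cols < 1L || is.na(n_rows) || n_rows < 1L)
    stop("n_cols and n_rows must be integers >= 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         n_cols = n_cols, n_rows = n_rows, cell_size = as.numeric(cell_size)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d cols x %d rows, cell %g m, origin (%g, %g), extent [%g, %g] x [%g, %g]\n",
    x$n_cols, x$n_rows, x$cell_size, x$x_min, x$y_min,
    x$x_min, x$x_min + x$n_cols * x$cell_size,
    x$y_min, x$y_min + x$n_rows * x$cell_size))
  invisible(x)
}

#' Cell centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return A two-column matrix (`x`, `y`) with one row per cell, in row-major
#'   order (row 0 first, columns left to right within a row).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  xs <- grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$y_min + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  cbind(x = rep(xs, times = grid$n_rows),
        y = rep(ys, each = grid$n_cols))
}

# Nearest-centre cell lookup. Returns 1-based (row, col) indices or signals an
# error at the first point outside the half-open extent.
cell_index <- function(grid, x, y) {
  jx <- floor((x - grid$x_min) / grid$cell_size)
  iy <- floor((y - grid$y_min) / grid$cell_size)
  bad <- which(jx < 0 | jx >= grid$n_cols | iy < 0 | iy >= grid$n_rows)
  if (length(bad) > 0L)
    stop(sprintf("point (%g, %g) falls outside the grid extent",
                 x[bad[1L]], y[bad[1L]]))
  cbind(row = as.integer(iy) + 1L, col = as.integer(jx) + 1L)
}

#' Construct a cover raster
#'
#' A `cover_raster` couples a [grid_spec()] with a matrix of per-cell values
#' (percent cover, a presence indicator or a richness count). `NA` entries
#' represent NODATA cells. The value matrix uses the internal lower-left
#' origin: `values[i, j]` is grid row `i - 1`, column `j - 1`.
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix of dimension `n_rows` x `n_cols`; `NA` marks
#'   NODATA.
#' @param taxon label of the variable held in the raster (may be `NA`).
#' @param provenance free-form character describing how the raster was made
#'   (method and configuration); kept as metadata only.
#' @return An object of class `cover_raster`.
#' @export
cover_raster <- function(grid, values, taxon = NA_character_,
                         provenance = character()) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop(sprintf("values must be a %d x %d matrix to match the grid",
                 grid$n_rows, grid$n_cols))
  structure(list(grid = grid, values = values, taxon = taxon,
                 provenance = provenance),
            class = "cover_raster")
}

#' @export
print.cover_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("cover_raster%s: %d x %d cells (%g m), %d NODATA\n",
              if (is.na(x$taxon)) "" else paste0(" [", x$taxon, "]"),
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(is.na(v))))
  fin <- v[is.finite(v)]
  if (length(fin) > 0L)
    cat(sprintf("  values: min %.3g, median %.3g, max %.3g\n",
                min(fin), stats::median(fin), max(fin)))
  if (length(x$provenance) > 0L)
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.cover_raster <- function(x, main = NULL, ...) {
  g <- x$grid
  xs <- g$x_min + (seq_len(g$n_cols) - 0.5) * g$cell_size
  ys <- g$y_min + (seq_len(g$n_rows) - 0.5) * g$cell_size
  graphics::image(xs, ys, t(x$values), asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = if (is.null(main)) x$taxon else main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Writes the standard `.asc` text format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of values).
#' The first data row written is the northernmost one, as the format
#' requires; `NA` cells are written as the NODATA value.
#'
#' @param raster a [cover_raster()].
#' @param path output file path.
#' @param nodata value standing in for `NA` cells (default -9999).
#' @param digits significant digits used when formatting values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path, nodata = -9999, digits = 6) {
  stopifnot(inherits(raster, "cover_raster"))
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$x_min),
    sprintf("yllcorner %.10g", g$y_min),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  v <- signif(raster$values, digits)
  v[is.na(v)] <- nodata                # after rounding: NODATA stays exact
  for (i in rev(seq_len(g$n_rows)))    # north-up on disk
    writeLines(paste(v[i, ], collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @param taxon optional taxon label to attach.
#' @return A [cover_raster()]; NODATA cells become `NA`.
#' @export
read_asc <- function(path, taxon = NA_character_) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) == 2L && tolower(parts[1L]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to lower-left origin
  m[m == nodata] <- NA_real_
  cover_raster(grid_spec(hdr$xllcorner, hdr$yllcorner, nc, nr, hdr$cellsize),
               m, taxon = taxon, provenance = paste("read from", basename(path)))
}
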