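#' Construct a georeferenced single-band grid
#'
#' The shared raster container of the package: a numeric matrix of cell
#' values (NA marks nodata), a square cell size in metres, and the map
#' coordinate of the top-left corner. Grids are north-up: row 1 is the
#' northernmost row and indices are matrix (row, col) pairs. All layers in
#' an analysis must share the same geometry; see [grids_aligned()].
#'
#' @param values numeric matrix; `NA` cells are nodata.
#' @param cell_size cell edge length in metres (default 1000, i.e. 1 km
#'   cells of 1 km2 each).
#' @param origin numeric length-2, map (x, y) of the top-left corner.
#' @param crs free-text label of the coordinate system.
#' @return An object of class `grid`.
#' @examples
#' g <- grid(matrix(1:12, 3, 4))
#' dim(g$values)
#' @export
grid <- function(values, cell_size = 1000,
                 origin = c(0, nrow(values) * cell_size),
                 crs = "local") {
  values <- as.matrix(values)
  storage.mode(values) <- if (is.integer(values)) "integer" else "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L)
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), crs = as.character(crs)[1L]),
            class = "grid")
}

#' @export
print.grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid> %d x %d cells, cell %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2], x$crs))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], nodata %d/%d\n", min(fin), max(fin),
                sum(is.na(v)), length(v)))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' @export
is_grid <- function(x) inherits(x, "grid")

#' Cell area of a grid in km2
#' @param g a [grid()].
#' @return Scalar area of one cell in km2 (1 at the 1000 m default).
#' @export
cell_area_km2 <- function(g) (g$cell_size / 1000)^2

#' Test that grids share one geometry
#'
#' @param ... grids.
#' @return TRUE if all grids have identical shape, cell size and origin.
#' @export
grids_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1L]]
  all(vapply(gs, function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      isTRUE(all.equal(g$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(g$origin, ref$origin))
  }, logical(1)))
}

stop_if_misaligned <- function(..., what = "grids") {
  if (!grids_aligned(...)) stop(what, " are not aligned (shape/cell/origin)")
  invisible(TRUE)
}

#' Map coordinates of cell centres
#' @param g a [grid()].
#' @return list with `x` (per column) and `y` (per row) centre coordinates.
#' @export
cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  list(x = g$origin[1] + (seq_len(nc) - 0.5) * cs,
       y = g$origin[2] - (seq_len(nr) - 0.5) * cs)
}

#' Convert map coordinates to (row, col) indices
#' @param g a [grid()].
#' @param x,y coordinate vectors.
#' @return integer matrix with columns `row`, `col`; points outside the
#'   grid get NA.
#' @export
xy_to_cell <- function(g, x, y) {
  cs <- g$cell_size
  col <- floor((x - g$origin[1]) / cs) + 1L
  row <- floor((g$origin[2] - y) / cs) + 1L
  bad <- row < 1L | row > nrow(g$values) | col < 1L | col > ncol(g$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read a single-band raster from an ESRI ASCII grid
#'
#' The package's raster interchange format is the plain-text ESRI ASCII
#' grid (`.asc`): a six-line header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by rows north to south. Values written
#' by [write_grid()] round-trip bit-exactly for integer grids and to full
#' double precision for floats.
#'
#' @param path file path to a `.asc` raster.
#' @return A [grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF input is not supported (single-band ESRI ASCII grid ",
         "required): ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (l in lines) {
    kv <- strsplit(trimws(l), "\\s+")[[1L]]
    if (length(kv) == 2L) hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster ", path, ": expected ", nr * nc, " values, found ",
         length(vals), " (single band required)")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (all(is.na(m) | m == round(m))) storage.mode(m) <- "integer"
  grid(m, cell_size = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize))
}

#' @rdname read_grid
#' @param g a [grid()] to write.
#' @return `write_grid` returns `path` invisibly.
#' @export
write_grid <- function(g, path) {
  stopifnot(is_grid(g))
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  nodata <- -9999
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", g$origin[1]),
           sprintf("yllcorner %.10f", g$origin[2] - nr * g$cell_size),
           sprintf("cellsize %.10f", g$cell_size),
           sprintf("NODATA_value %d", nodata))
  fmt <- if (is.integer(v)) function(x) sprintf("%d", x)
         else function(x) sprintf("%.17g", x)
  rows <- vapply(seq_len(nr), function(i) {
    r <- v[i, ]
    out <- fmt(r)
    out[is.na(r)] <- as.character(nodata)
    paste(out, collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
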