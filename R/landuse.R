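#' Land-use legend
#'
#' The six broad land-use classes used throughout the pipeline, coded 1-6.
#' @return Named integer vector mapping class name to code.
#' @export
landuse_legend <- function() {
  c(cropland = 1L, woodland = 2L, grassland = 3L, water = 4L,
    construction = 5L, unused = 6L)
}

#' Construct a categorical land-use map
#'
#' @param g a [grid()] of integer class codes.
#' @param legend named integer vector (name -> code); defaults to the
#'   six-class legend of [landuse_legend()].
#' @return An object of class `landuse_map` with fields `grid` and
#'   `legend`.
#' @export
landuse_map <- function(g, legend = landuse_legend()) {
  stopifnot(is_grid(g))
  v <- g$values[!is.na(g$values)]
  if (length(v) && !all(v %in% legend))
    stop("landuse_map: values outside legend codes: ",
         paste(sort(unique(v[!v %in% legend])), collapse = ", "))
  storage.mode(g$values) <- "integer"
  structure(list(grid = g, legend = legend), class = "landuse_map")
}

#' @export
print.landuse_map <- function(x, ...) {
  cat("<landuse_map>\n")
  tab <- table(factor(x$grid$values, levels = x$legend,
                      labels = names(x$legend)))
  print(round(prop.table(tab), 3))
  invisible(x)
}

#' Binary mask of one or more land-use classes
#' @param lu a [landuse_map()].
#' @param classes character names or integer codes.
#' @return A [grid()] with 1 where the cell is any of `classes`, 0
#'   elsewhere, nodata preserved.
#' @export
landuse_mask <- function(lu, classes) {
  codes <- if (is.character(classes)) lu$legend[classes] else as.integer(classes)
  if (anyNA(codes)) stop("unknown land-use class in: ",
                         paste(classes, collapse = ", "))
  v <- lu$grid$values
  m <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  m[ok] <- as.integer(v[ok] %in% codes)
  grid(m, cell_size = lu$grid$cell_size, origin = lu$grid$origin,
       crs = lu$grid$crs)
}
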