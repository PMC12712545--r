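#' Class breaks for grid classification
#'
#' A `class_breaks` object holds the k+1 ascending edges delimiting k
#' classes plus the method that produced them. Classification follows the
#' half-open convention: class i covers `[edges[i], edges[i+1])`, lower
#' edge inclusive, except the final class which also includes its upper
#' edge so the global maximum is not orphaned.
#'
#' @name class_breaks
NULL

new_breaks <- function(edges, method, labels = NULL) {
  edges <- as.numeric(edges)
  k <- length(edges) - 1L
  degenerate <- k >= 1L && any(diff(edges) <= 0)
  if (is.null(labels)) labels <- paste0("class_", seq_len(max(k, 1L)))
  structure(list(edges = edges, method = method, k = max(k, 1L),
                 labels = labels, degenerate = degenerate),
            class = "class_breaks")
}

#' @export
print.class_breaks <- function(x, ...) {
  cat(sprintf("<class_breaks> %s, %d classes\n  edges: %s\n", x$method, x$k,
              paste(signif(x$edges, 6), collapse = ", ")))
  invisible(x)
}

#' Equal-interval class breaks
#'
#' Divides `[min, max]` (or caller-supplied `bounds`) into `k` equal-width
#' classes, the scheme used to grade habitat quality into five levels
#' (high 0.8-1 down to low 0-0.2).
#'
#' @param values numeric values to classify (ignored when `bounds` given,
#'   beyond requiring at least one finite value).
#' @param k number of classes (>= 1).
#' @param bounds optional fixed `c(lo, hi)` overriding the data range,
#'   e.g. `c(0, 1)` for quality scores.
#' @param labels optional class labels, low to high.
#' @return A `class_breaks` object with `k + 1` edges.
#' @examples
#' equal_interval_breaks(bounds = c(0, 1), k = 5)$edges
#' @export
equal_interval_breaks <- function(values = NULL, k = 5L, bounds = NULL,
                                  labels = NULL) {
  stopifnot(k >= 1)
  if (is.null(bounds)) {
    v <- values[is.finite(values)]
    if (!length(v)) stop("equal_interval_breaks: no finite values")
    bounds <- range(v)
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  if (hi == lo) {
    warning("equal_interval_breaks: max == min; single degenerate class")
    return(new_breaks(c(lo, lo), "equal_interval", labels = labels[1L]))
  }
  edges <- lo + (0:k) * (hi - lo) / k
  edges[k + 1L] <- hi
  new_breaks(edges, "equal_interval", labels = labels)
}

#' Natural-breaks (Jenks) class breaks
#'
#' Exact Fisher dynamic-programming partition of the values into `k`
#' contiguous classes minimising total within-class sum of squared
#' deviations. Deterministic for fixed input (no k-means heuristic). Used
#' for carbon-storage zoning and habitat-suitability levels.
#'
#' @inheritParams equal_interval_breaks
#' @return A `class_breaks` object; interior edges sit at the minimum value
#'   of each upper class so the half-open classification convention
#'   reproduces the optimal partition exactly.
#' @examples
#' jenks_breaks(c(1, 2, 3, 100, 101, 102), k = 2)$edges
#' @export
jenks_breaks <- function(values, k, labels = NULL) {
  v <- sort(values[is.finite(values)])
  if (!length(v)) stop("jenks_breaks: no finite values")
  ndist <- length(unique(v))
  if (ndist < k)
    stop("jenks_breaks: ", ndist, " distinct values < ", k, " classes")
  if (k == 1L) return(new_breaks(range(v), "jenks", labels = labels))
  starts <- .fisher_jenks_cpp(v, as.integer(k))
  edges <- c(v[1L], v[starts[-1L]], v[length(v)])
  new_breaks(edges, "jenks", labels = labels)
}

#' Classify a grid by class breaks
#'
#' Maps each non-nodata cell to its class index 1..k under the half-open
#' convention (`[e_i, e_{i+1})`, final class closed above). Out-of-range
#' values are clamped into the end classes with a warning reporting how
#' many cells were affected.
#'
#' @param g a [grid()].
#' @param breaks a `class_breaks` object.
#' @return A [grid()] of integer class indices, nodata preserved.
#' @export
classify <- function(g, breaks) {
  stopifnot(is_grid(g), inherits(breaks, "class_breaks"))
  v <- g$values
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  if (any(ok)) {
    if (breaks$degenerate) {
      out[ok] <- 1L
    } else {
      e <- breaks$edges
      k <- breaks$k
      x <- v[ok]
      n_out <- sum(x < e[1L] | x > e[k + 1L])
      if (n_out > 0)
        warning("classify: ", n_out, " cell(s) outside break range; clamped")
      idx <- findInterval(x, e, rightmost.closed = TRUE)
      idx[idx < 1L] <- 1L
      idx[idx > k] <- k
      out[ok] <- as.integer(idx)
    }
  }
  grid(out, cell_size = g$cell_size, origin = g$origin, crs = g$crs)
}

#' Serialize class breaks to YAML
#' @param breaks a `class_breaks` object.
#' @param path output file.
#' @export
write_breaks <- function(breaks, path) {
  yaml::write_yaml(list(method = breaks$method, k = breaks$k,
                        edges = breaks$edges, labels = breaks$labels), path)
  invisible(path)
}

#' @rdname write_breaks
#' @export
read_breaks <- function(path) {
  y <- yaml::read_yaml(path)
  new_breaks(y$edges, y$method, labels = unlist(y$labels))
}
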