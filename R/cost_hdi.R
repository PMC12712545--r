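#' Land-use disturbance score surface
#'
#' Per-cell lookup of a disturbance intensity per land-use class; the
#' land-use component of the human-disturbance index.
#'
#' @param lu a [landuse_map()].
#' @param score_table named numeric vector (class name -> score). The
#'   default ranks construction highest and woodland/water lowest.
#' @return A [grid()] of disturbance scores.
#' @export
landuse_disturbance <- function(lu, score_table = c(
    construction = 1.0, cropland = 0.6, unused = 0.3, grassland = 0.2,
    woodland = 0.1, water = 0.1)) {
  cls <- names(lu$legend)[match(lu$grid$values, lu$legend)]
  present <- unique(cls[!is.na(cls)])
  missing <- setdiff(present, names(score_table))
  if (length(missing))
    stop("landuse_disturbance: no score for class(es): ",
         paste(missing, collapse = ", "))
  v <- matrix(score_table[cls], nrow(lu$grid$values), ncol(lu$grid$values))
  grid(v, cell_size = lu$grid$cell_size, origin = lu$grid$origin,
       crs = lu$grid$crs)
}

#' Entropy weights for disturbance indicators
#'
#' The entropy-weight method: each indicator is min-max standardised over
#' the n non-nodata cells (inverted for `direction = "cost"`), converted
#' to a share distribution p_ij = x_ij / sum_i x_ij, scored by Shannon
#' entropy e_j = -(1/ln n) sum p ln p (0 ln 0 := 0), and weighted
#' W_j = (1 - e_j) / sum_k (1 - e_k): the less even an indicator's
#' spatial distribution, the more information it carries and the more
#' weight it gets.
#'
#' @param indicators named list of aligned [grid()]s.
#' @param direction per indicator `"benefit"` (high value = high
#'   disturbance) or `"cost"` (inverted); recycled.
#' @return list `weights` (sums to 1), `entropies`.
#' @export
entropy_weights <- function(indicators, direction = "benefit") {
  stopifnot(length(indicators) >= 1L)
  direction <- rep_len(direction, length(indicators))
  ref <- indicators[[1L]]
  for (g in indicators) stop_if_misaligned(ref, g, what = "indicators")
  ok <- Reduce(`&`, lapply(indicators, function(g) !is.na(g$values)))
  n <- sum(ok)
  ent <- vapply(seq_along(indicators), function(j) {
    x <- indicators[[j]]$values[ok]
    rng <- range(x)
    if (diff(rng) == 0) return(1)             # constant: zero information
    z <- (x - rng[1L]) / diff(rng)
    if (direction[j] == "cost") z <- 1 - z
    s <- sum(z)
    if (s == 0) return(1)
    p <- z / s
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  }, numeric(1))
  info <- 1 - ent
  if (all(info <= 0))
    stop("entropy_weights: all indicators are constant")
  if (any(ent >= 1 - 1e-15))
    warning("entropy_weights: constant indicator(s) received weight 0")
  w <- info / sum(info)
  w[w < 0] <- 0
  w <- w / sum(w)
  names(w) <- names(ent) <- names(indicators)
  list(weights = w, entropies = ent)
}

#' Human-disturbance index (HDI) cost surface
#'
#' Weighted sum of the min-max standardised indicators, HDI =
#' sum_j W_j x'_ij, in [0, 1]. Used as the planning-unit cost.
#'
#' @param indicators named list of aligned [grid()]s.
#' @param weights output of [entropy_weights()] (or a bare named vector
#'   summing to 1).
#' @param direction as in [entropy_weights()].
#' @return A [grid()] in [0, 1].
#' @export
hdi <- function(indicators, weights = entropy_weights(indicators),
                direction = "benefit") {
  w <- if (is.list(weights)) weights$weights else weights
  if (length(w) != length(indicators))
    stop("hdi: ", length(w), " weights for ", length(indicators),
         " indicators")
  direction <- rep_len(direction, length(indicators))
  ref <- indicators[[1L]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (j in seq_along(indicators)) {
    x <- indicators[[j]]$values
    rng <- range(x, na.rm = TRUE)
    z <- if (diff(rng) == 0) x * 0 else (x - rng[1L]) / diff(rng)
    if (direction[j] == "cost") z <- 1 - z
    acc <- acc + w[j] * z
  }
  acc[is.na(ref$values)] <- NA
  grid(acc, cell_size = ref$cell_size, origin = ref$origin, crs = ref$crs)
}
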