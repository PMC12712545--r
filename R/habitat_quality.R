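#' Threat specification for habitat-quality degradation
#'
#' @param name threat name (must match a sensitivity-table column).
#' @param weight relative weight w_r >= 0 (normalised over all threats).
#' @param max_dist_km maximum influence distance in km.
#' @param decay distance-decay law: `"linear"` (1 - d/d_max) or
#'   `"exponential"` (exp(-2.99 d / d_max), ~0.05 at d_max).
#' @param source a [grid()] of threat intensity in [0, 1] (nodata treated
#'   as absence).
#' @return A `threat_spec` object.
#' @export
threat_spec <- function(name, weight, max_dist_km, decay = c("linear", "exponential"),
                        source) {
  decay <- match.arg(decay)
  stopifnot(weight >= 0, max_dist_km > 0, is_grid(source))
  structure(list(name = name, weight = weight, max_dist_km = max_dist_km,
                 decay = decay, source = source), class = "threat_spec")
}

#' Habitat-score and sensitivity lookup table
#'
#' @param habitat named numeric vector: habitat suitability score H_j in
#'   [0, 1] per land-use class name.
#' @param sensitivity numeric matrix in [0, 1], rows = land-use class
#'   names, columns = threat names (S_jr).
#' @param accessibility optional [grid()] beta in [0, 1] modulating threat
#'   access per cell (default 1 everywhere).
#' @return A `sensitivity_table` object.
#' @export
sensitivity_table <- function(habitat, sensitivity, accessibility = NULL) {
  stopifnot(all(habitat >= 0 & habitat <= 1),
            all(sensitivity >= 0 & sensitivity <= 1),
            !is.null(names(habitat)), !is.null(rownames(sensitivity)))
  if (!all(rownames(sensitivity) %in% names(habitat)))
    stop("sensitivity rows must be a subset of habitat-score classes")
  structure(list(habitat = habitat, sensitivity = sensitivity,
                 accessibility = accessibility), class = "sensitivity_table")
}

#' Packaged default threat parameters and sensitivities
#'
#' A literature-typical parameterisation for a six-class agricultural/
#' forest landscape: cropland is a short-range linear threat, built-up
#' land a long-range exponential one, roads intermediate. Override freely;
#' nothing downstream assumes these values.
#'
#' @param threat_sources named list of source [grid()]s with any of the
#'   names `cropland`, `construction`, `road`.
#' @return list of [threat_spec()]s.
#' @export
default_threats <- function(threat_sources) {
  spec <- list(
    cropland = list(weight = 0.6, max_dist_km = 1, decay = "linear"),
    construction = list(weight = 1.0, max_dist_km = 8, decay = "exponential"),
    road = list(weight = 0.7, max_dist_km = 2, decay = "linear"))
  out <- list()
  for (nm in names(threat_sources)) {
    p <- spec[[nm]]
    if (is.null(p)) p <- list(weight = 0.5, max_dist_km = 2, decay = "linear")
    out[[nm]] <- threat_spec(nm, p$weight, p$max_dist_km, p$decay,
                             threat_sources[[nm]])
  }
  out
}

#' @rdname default_threats
#' @export
default_sensitivity <- function() {
  classes <- names(landuse_legend())
  habitat <- c(cropland = 0.3, woodland = 1.0, grassland = 0.8,
               water = 0.9, construction = 0.0, unused = 0.1)
  sens <- rbind(
    cropland     = c(0.0, 0.5, 0.3),
    woodland     = c(0.5, 0.9, 0.7),
    grassland    = c(0.4, 0.7, 0.5),
    water        = c(0.6, 0.8, 0.5),
    construction = c(0.0, 0.0, 0.0),
    unused       = c(0.1, 0.2, 0.1))
  colnames(sens) <- c("cropland", "construction", "road")
  sensitivity_table(habitat[classes], sens[classes, ])
}

#' Read threat specifications from a YAML file
#'
#' The file holds one entry per threat with fields `weight`,
#' `max_dist_km`, `decay` and `source` (a raster path, resolved relative
#' to the YAML file's directory).
#'
#' @param path path to `threats.yaml`.
#' @return list of [threat_spec()]s.
#' @export
read_threats <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(names(y), function(nm) {
    e <- y[[nm]]
    src <- if (file.exists(e$source)) e$source else file.path(base, e$source)
    threat_spec(nm, e$weight, e$max_dist_km, e$decay, read_grid(src))
  })
}

#' Read a habitat-score / sensitivity table from CSV
#'
#' Rows are land-use classes; the `HABITAT` column holds H_j and every
#' `S_<threat>` column one threat's sensitivity.
#'
#' @param path path to `sensitivity.csv` (first column = class name).
#' @return A [sensitivity_table()].
#' @export
read_sensitivity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L)
  if (!"HABITAT" %in% names(df))
    stop("sensitivity.csv needs a HABITAT column")
  s_cols <- grep("^S_", names(df), value = TRUE)
  sens <- as.matrix(df[, s_cols, drop = FALSE])
  colnames(sens) <- sub("^S_", "", s_cols)
  sensitivity_table(stats::setNames(df$HABITAT, rownames(df)), sens)
}

# Sum shifted copies of `m` weighted by a distance kernel. kernel: matrix
# with columns di, dj, w. Cells outside the grid contribute nothing.
kernel_convolve <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    di <- kernel[i, 1L]; dj <- kernel[i, 2L]; w <- kernel[i, 3L]
    if (abs(di) >= nr || abs(dj) >= nc) next
    r_dst <- max(1L, 1L - di):min(nr, nr - di)
    c_dst <- max(1L, 1L - dj):min(nc, nc - dj)
    acc[r_dst, c_dst] <- acc[r_dst, c_dst] + w * m[r_dst + di, c_dst + dj]
  }
  acc
}

#' Distance-decayed impact field of one threat
#'
#' For every cell the decayed intensities of all source cells within the
#' threat's maximum distance are summed and divided by the number of
#' contributing source cells, so the impact lies in [0, 1] when
#' intensities do. Distances are Euclidean centre-to-centre.
#'
#' @param threat a [threat_spec()].
#' @return A [grid()] of impact values in [0, 1].
#' @export
threat_impact <- function(threat) {
  src <- threat$source
  cell_km <- src$cell_size / 1000
  v <- src$values
  v[is.na(v)] <- 0
  if (all(v == 0)) {
    warning("threat_impact: empty source raster for '", threat$name, "'")
    return(grid(matrix(0, nrow(v), ncol(v)), cell_size = src$cell_size,
                origin = src$origin, crs = src$crs))
  }
  rad <- floor(threat$max_dist_km / cell_km + 1e-9)
  off <- expand.grid(di = -rad:rad, dj = -rad:rad)
  d <- cell_km * sqrt(off$di^2 + off$dj^2)
  keep <- d <= threat$max_dist_km + 1e-12
  off <- off[keep, ]; d <- d[keep]
  w <- if (threat$decay == "linear") 1 - d / threat$max_dist_km
       else exp(-2.99 * d / threat$max_dist_km)
  num <- kernel_convolve(v, cbind(off$di, off$dj, w))
  den <- kernel_convolve((v > 0) * 1, cbind(off$di, off$dj, 1))
  imp <- ifelse(den > 0, num / den, 0)
  grid(imp, cell_size = src$cell_size, origin = src$origin, crs = src$crs)
}

#' Threat-weighted habitat degradation
#'
#' D_x = sum_r (w_r / sum w) * impact_r(x) * beta_x * S_{j(x),r}, where
#' j(x) is the land-use class of cell x. Degradation is defined on every
#' non-nodata cell; the habitat score enters only through [hq_quality()].
#'
#' @param threats list of [threat_spec()]s.
#' @param sens a [sensitivity_table()].
#' @param lu a [landuse_map()].
#' @return A [grid()] of degradation D >= 0.
#' @export
degradation <- function(threats, sens, lu) {
  w_tot <- sum(vapply(threats, `[[`, numeric(1), "weight"))
  if (w_tot <= 0) stop("degradation: total threat weight is zero")
  g <- lu$grid
  classes <- names(lu$legend)[match(g$values, lu$legend)]
  beta <- if (is.null(sens$accessibility)) 1 else sens$accessibility$values
  D <- matrix(0, nrow(g$values), ncol(g$values))
  for (th in threats) {
    stop_if_misaligned(g, th$source, what = "threat source and land use")
    imp <- threat_impact(th)$values
    s_col <- sens$sensitivity[, th$name]
    S <- matrix(s_col[classes], nrow(g$values), ncol(g$values))
    S[is.na(S)] <- 0
    D <- D + (th$weight / w_tot) * imp * beta * S
  }
  D[is.na(g$values)] <- NA
  grid(D, cell_size = g$cell_size, origin = g$origin, crs = g$crs)
}

#' Habitat quality from degradation (half-saturation transform)
#'
#' Q_x = H_j * (1 - D^z / (D^z + k^z)). With `k = "auto"` the
#' half-saturation constant is set to half the maximum observed
#' degradation, so the most degraded cell retains H/ (1 + 2^z / (2^z+1))
#' of its score and a cell at D = k exactly half. Quality is graded into
#' five equal-interval levels on [0, 1]; the top two levels form the
#' high-value habitat mask.
#'
#' @param D degradation [grid()] (from [degradation()]).
#' @param lu a [landuse_map()].
#' @param sens a [sensitivity_table()] (supplies the habitat scores H_j).
#' @param z shape constant of the saturation curve (default 2.5).
#' @param k half-saturation constant, or `"auto"` for max(D)/2.
#' @return An `hq_result` list: `quality`, `degradation`, `classes`,
#'   `high_value_mask` grids, constants `k`, `z`, `mean_hqi`, and
#'   `class_fractions`.
#' @export
hq_quality <- function(D, lu, sens, z = 2.5, k = "auto") {
  stop_if_misaligned(D, lu$grid, what = "degradation and land use")
  dv <- D$values
  if (any(dv < 0, na.rm = TRUE)) stop("hq_quality: negative degradation")
  if (identical(k, "auto")) {
    dmax <- max(dv, na.rm = TRUE)
    if (dmax == 0) {
      warning("hq_quality: no degradation anywhere; k set to 0.5")
      k <- 0.5
    } else k <- dmax / 2
  }
  classes_j <- names(lu$legend)[match(lu$grid$values, lu$legend)]
  H <- matrix(sens$habitat[classes_j], nrow(dv), ncol(dv))
  Q <- H * (1 - dv^z / (dv^z + k^z))
  Q[is.na(lu$grid$values)] <- NA
  qg <- grid(Q, cell_size = D$cell_size, origin = D$origin, crs = D$crs)
  lv <- c("low", "moderately_low", "medium", "moderately_high", "high")
  brk <- equal_interval_breaks(bounds = c(0, 1), k = 5L, labels = lv)
  cls <- classify(qg, brk)
  hv <- cls
  hv$values <- ifelse(is.na(cls$values), NA_integer_,
                      as.integer(cls$values >= 4L))
  fr <- prop.table(table(factor(cls$values, levels = 1:5, labels = lv)))
  structure(list(quality = qg, degradation = D, classes = cls,
                 high_value_mask = hv, k = k, z = z,
                 mean_hqi = mean(Q, na.rm = TRUE),
                 class_fractions = fr, breaks = brk),
            class = "hq_result")
}

#' Per-cell habitat-quality change between two periods
#'
#' @param q_t0,q_t1 quality [grid()]s of the earlier/later period.
#' @param tol absolute change below which a cell counts as stable
#'   (default 0.01, suppressing floating-point churn).
#' @return list with `change` grid coded -1 (degraded), 0 (stable),
#'   1 (improved) and `fractions` of each state over non-nodata cells.
#' @export
hq_change <- function(q_t0, q_t1, tol = 0.01) {
  stop_if_misaligned(q_t0, q_t1, what = "quality grids")
  d <- q_t1$values - q_t0$values
  ch <- ifelse(d > tol, 1L, ifelse(d < -tol, -1L, 0L))
  g <- grid(ch, cell_size = q_t0$cell_size, origin = q_t0$origin,
            crs = q_t0$crs)
  tab <- table(factor(ch[!is.na(ch)], levels = c(-1, 0, 1),
                      labels = c("degraded", "stable", "improved")))
  list(change = g, fractions = prop.table(tab))
}
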