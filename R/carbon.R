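#' Carbon density table over land-use classes
#'
#' Per class the four ecosystem carbon pools (aboveground biomass,
#' belowground biomass, soil organic carbon, dead organic matter) in
#' t/ha; the class density c_i is their sum.
#'
#' @param df data.frame with columns `class`, `c_above`, `c_below`,
#'   `c_soil`, `c_dead` (one row per land-use class name). Defaults to a
#'   packaged literature-typical table for the six-class legend.
#' @return A `carbon_density_table` with a derived `density` column.
#' @export
carbon_density_table <- function(df = default_carbon_densities()) {
  need <- c("class", "c_above", "c_below", "c_soil", "c_dead")
  stopifnot(all(need %in% names(df)))
  pools <- as.matrix(df[, c("c_above", "c_below", "c_soil", "c_dead")])
  if (any(pools < 0)) stop("carbon pools must be non-negative")
  df$density <- rowSums(pools)
  structure(df, class = c("carbon_density_table", "data.frame"))
}

#' @rdname carbon_density_table
#' @export
default_carbon_densities <- function() {
  data.frame(
    class  = c("cropland", "woodland", "grassland", "water",
               "construction", "unused"),
    c_above = c(5.7, 42.8, 3.0, 0.2, 0.9, 0.5),
    c_below = c(1.1, 8.4, 6.8, 0.0, 0.0, 0.0),
    c_soil  = c(108.4, 158.8, 99.9, 60.0, 40.0, 30.0),
    c_dead  = c(0.0, 2.4, 0.0, 0.0, 0.0, 0.0))
}

#' Carbon density map, total stock and storage zones
#'
#' Each cell takes the summed pool density of its land-use class; the
#' landscape total is sum_i c_i * R_i with R_i the class area in ha.
#' Cells are zoned into six categories: a dedicated "none" zone for zero
#' density plus up to five natural-breaks classes (low .. high) over the
#' distinct positive densities, collapsing gracefully when fewer than
#' five distinct positive densities exist.
#'
#' @param lu a [landuse_map()].
#' @param table a [carbon_density_table()].
#' @return A `carbon_result`: `density_grid` (t/ha), `total_C` (t),
#'   `zones` grid (0 = none, then 1 = low .. up to 5 = high),
#'   `zone_labels`, `zone_shares`.
#' @export
carbon_map <- function(lu, table = carbon_density_table()) {
  g <- lu$grid
  codes <- sort(unique(g$values[!is.na(g$values)]))
  cls <- names(lu$legend)[match(codes, lu$legend)]
  missing <- cls[!cls %in% table$class]
  if (length(missing))
    stop("carbon_map: no density row for land-use class(es): ",
         paste(missing, collapse = ", "))
  dens_by_class <- stats::setNames(table$density, table$class)
  cell_names <- names(lu$legend)[match(g$values, lu$legend)]
  dv <- matrix(dens_by_class[cell_names], nrow(g$values), ncol(g$values))
  dv[is.na(g$values)] <- NA
  density_grid <- grid(dv, cell_size = g$cell_size, origin = g$origin,
                       crs = g$crs)
  area_ha <- cell_area_km2(g) * 100
  counts <- table(factor(cell_names, levels = table$class))
  total_C <- sum(table$density * as.numeric(counts) * area_ha)

  pos <- sort(unique(dv[!is.na(dv) & dv > 0]))
  kz <- min(5L, length(pos))
  zones <- matrix(NA_integer_, nrow(dv), ncol(dv))
  ok <- !is.na(dv)
  zones[ok & dv == 0] <- 0L
  if (kz >= 1L) {
    brk <- if (kz == 1L) new_breaks(range(pos), "jenks")
           else jenks_breaks(pos, kz)
    idx <- findInterval(dv[ok & dv > 0], brk$edges, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L; idx[idx > kz] <- kz
    zones[ok & dv > 0] <- as.integer(idx)
  }
  all_labels <- c("low", "relatively_low", "moderate", "relatively_high",
                  "high")
  zone_labels <- c("none", all_labels[seq_len(kz)])
  zg <- grid(zones, cell_size = g$cell_size, origin = g$origin, crs = g$crs)
  shares <- prop.table(table(factor(zones[ok], levels = 0:kz,
                                    labels = zone_labels)))
  structure(list(density_grid = density_grid, total_C = total_C,
                 zones = zg, zone_labels = zone_labels,
                 zone_shares = shares, n_zones = kz),
            class = "carbon_result")
}

#' High-carbon storage mask
#'
#' @param cr a `carbon_result`.
#' @param top number of top zones counted as "high-carbon" (default 2:
#'   high + relatively high).
#' @return 0/1 [grid()].
#' @export
carbon_high_mask <- function(cr, top = 2L) {
  z <- cr$zones$values
  m <- ifelse(is.na(z), NA_integer_, as.integer(z > cr$n_zones - top))
  grid(m, cell_size = cr$zones$cell_size, origin = cr$zones$origin,
       crs = cr$zones$crs)
}

#' Carbon-stock change between two periods
#'
#' @param r_t0,r_t1 `carbon_result`s of the earlier/later period.
#' @return list with `delta_total` (t) and `delta_grid` (t/ha per cell).
#' @export
carbon_change <- function(r_t0, r_t1) {
  stop_if_misaligned(r_t0$density_grid, r_t1$density_grid,
                     what = "carbon grids")
  dg <- r_t1$density_grid$values - r_t0$density_grid$values
  list(delta_total = r_t1$total_C - r_t0$total_C,
       delta_grid = grid(dg, cell_size = r_t0$density_grid$cell_size,
                         origin = r_t0$density_grid$origin,
                         crs = r_t0$density_grid$crs))
}
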