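#' Eight-category species / habitat / carbon overlay
#'
#' Crosses three binary masks -- species high-suitability (union over
#' species), high-value habitat, and high-carbon zones -- into the 2^3
#' truth-table categories used to read conservation priorities off the
#' map.
#'
#' @param species_high,habitat_high,carbon_high aligned 0/1 [grid()]s.
#' @return An `overlay_map`: `categories` grid (1..8), `labels`,
#'   `shares` (area fraction per category, summing to 1 over non-nodata
#'   cells).
#' @export
overlay_priorities <- function(species_high, habitat_high, carbon_high) {
  stop_if_misaligned(species_high, habitat_high, carbon_high,
                     what = "overlay masks")
  s <- species_high$values > 0
  h <- habitat_high$values > 0
  c_ <- carbon_high$values > 0
  labels <- c("hotspot", "species_habitat", "species_carbon",
              "habitat_carbon", "species_only", "habitat_only",
              "carbon_only", "non_significant")
  cat <- ifelse(s & h & c_, 1L,
         ifelse(s & h, 2L,
         ifelse(s & c_, 3L,
         ifelse(h & c_, 4L,
         ifelse(s, 5L,
         ifelse(h, 6L,
         ifelse(c_, 7L, 8L)))))))
  cat[is.na(s) | is.na(h) | is.na(c_)] <- NA_integer_
  g <- grid(cat, cell_size = species_high$cell_size,
            origin = species_high$origin, crs = species_high$crs)
  shares <- prop.table(table(factor(cat[!is.na(cat)], levels = 1:8,
                                    labels = labels)))
  structure(list(categories = g, labels = labels, shares = shares),
            class = "overlay_map")
}

#' Persistent conservation gaps across periods
#'
#' Intersects per-period gap-unit sets: a unit is a persistent gap only
#' if it is flagged as a gap in every period.
#'
#' @param per_period named list (period -> vector of gap unit ids).
#' @return list `persistent` (intersection), `per_period_counts`,
#'   `persistent_count`.
#' @export
persistent_gaps <- function(per_period) {
  if (length(per_period) < 2L)
    stop("persistent_gaps: need at least 2 periods")
  persistent <- Reduce(intersect, per_period)
  list(persistent = persistent,
       per_period_counts = vapply(per_period, length, integer(1)),
       persistent_count = length(persistent))
}
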