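#' Label connected patches in a binary mask
#'
#' Connected-component labelling of the true cells (queen = 8-neighbour
#' by default, the Fragstats patch rule). Labels are deterministic:
#' numbered by column-major scan order of each patch's first cell.
#'
#' @param mask a [grid()] with 0/1 (or logical) values; NA = nodata.
#' @param connectivity `"queen"` (default) or `"rook"`.
#' @return list `labels` (integer grid, 0 outside patches) and `np`.
#' @export
label_patches <- function(mask, connectivity = c("queen", "rook")) {
  connectivity <- match.arg(connectivity)
  M <- mask$values
  nr <- nrow(M); nc <- ncol(M)
  tr <- !is.na(M) & M > 0
  n_true <- sum(tr)
  lab <- matrix(0L, nr, nc)
  lab[is.na(M)] <- NA_integer_
  if (n_true == 0L)
    return(list(labels = grid(lab, cell_size = mask$cell_size,
                              origin = mask$origin), np = 0L))
  rank_of <- matrix(0L, nr, nc)
  rank_of[tr] <- seq_len(n_true)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0)
  for (o in offs) {
    di <- o[1L]; dj <- o[2L]
    if (di >= nr || abs(dj) >= nc) next
    r1 <- 1L:(nr - di)
    c1 <- if (dj >= 0L) 1L:(nc - dj) else (1L - dj):nc
    a <- tr[r1, c1, drop = FALSE] & tr[r1 + di, c1 + dj, drop = FALSE]
    if (!any(a)) next
    ra <- rank_of[r1, c1, drop = FALSE][a]
    rb <- rank_of[r1 + di, c1 + dj, drop = FALSE][a]
    from <- c(from, ra); to <- c(to, rb)
  }
  g <- igraph::make_graph(rbind(from, to), n = n_true, directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by first appearance in scan order
  first <- match(unique(comp), comp)
  newid <- integer(max(comp))
  newid[comp[sort(first)]] <- seq_along(first)
  lab[tr] <- newid[comp]
  list(labels = grid(lab, cell_size = mask$cell_size, origin = mask$origin),
       np = length(first))
}

#' Patch metrics of a binary mask
#'
#' The four landscape metrics underlying the composite fragmentation
#' index: patch count NP (queen connectivity), patch density PD
#' (patches/km2 of window), mean patch area AREA_MN (km2) and aggregation
#' index AI = 100 g / g_max, where g counts rook like-adjacencies among
#' true cells and g_max is the largest-integer-square maximum for the
#' same cell count (with A cells, n = floor(sqrt(A)), m = A - n^2:
#' g_max = 2n(n-1) if m = 0; + 2m - 1 if m <= n; + 2m - 2 if m > n).
#'
#' @param mask a [grid()] 0/1 mask.
#' @param window_area_km2 reference area for PD (defaults to the mask's
#'   full extent).
#' @return list `np`, `pd`, `area_mn`, `ai` (zeroes for an empty mask).
#' @export
patch_metrics <- function(mask, window_area_km2 = NULL) {
  M <- mask$values
  tr <- !is.na(M) & M > 0
  if (is.null(window_area_km2))
    window_area_km2 <- length(M) * cell_area_km2(mask)
  A <- sum(tr)
  if (A == 0L) return(list(np = 0L, pd = 0, area_mn = 0, ai = 0))
  np <- label_patches(mask, "queen")$np
  area_mn <- A * cell_area_km2(mask) / np
  nr <- nrow(M); nc <- ncol(M)
  g_adj <- sum(tr[, -nc, drop = FALSE] & tr[, -1L, drop = FALSE]) +
           sum(tr[-nr, , drop = FALSE] & tr[-1L, , drop = FALSE])
  n <- floor(sqrt(A)); m <- A - n^2
  g_max <- if (m == 0) 2 * n * (n - 1)
           else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
           else 2 * n * (n - 1) + 2 * m - 2
  ai <- if (g_max > 0) 100 * g_adj / g_max else 0
  list(np = np, pd = np / window_area_km2, area_mn = area_mn, ai = ai)
}

# split a grid into non-overlapping full windows; returns data.frame of
# window row/col block indices and the row/col cell ranges
window_index <- function(g, w) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  expand.grid(wr = seq_len(nr %/% w), wc = seq_len(nc %/% w))
}

window_sub <- function(g, wr, wc, w) {
  rows <- ((wr - 1L) * w + 1L):(wr * w)
  cols <- ((wc - 1L) * w + 1L):(wc * w)
  grid(g$values[rows, cols, drop = FALSE], cell_size = g$cell_size,
       origin = c(g$origin[1] + (cols[1L] - 1L) * g$cell_size,
                  g$origin[2] - (rows[1L] - 1L) * g$cell_size))
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(NA_real_, length(x)))  # degenerate
  (x - rng[1L]) / diff(rng)
}

#' Composite landscape fragmentation index over spatial windows
#'
#' Each period's mask is tiled into non-overlapping windows; the four
#' patch metrics are computed per window; NP and PD are min-max
#' normalised over ALL windows of ALL periods jointly (so period means
#' are comparable on one scale), AREA_MN and AI are inverted after the
#' same normalisation (they fall with fragmentation); the index is the
#' equal-weight mean of the four components and lies in [0, 1]. A metric
#' constant across every window carries no ordering information and its
#' component is fixed at the neutral value 0.5 (with a warning). The
#' period mean is taken over windows containing any true cell.
#'
#' @param masks named list (period -> 0/1 [grid()]).
#' @param window_size_cells square window edge in cells (>= 10,
#'   default 20).
#' @return Named list per period: `windows` data.frame (per-window
#'   metrics, components, `clfi`), `clfi_grid` (window value painted onto
#'   cells), `mean_clfi`.
#' @export
clfi <- function(masks, window_size_cells = 20L) {
  stopifnot(length(masks) >= 1L, window_size_cells >= 10L)
  w <- as.integer(window_size_cells)
  ref <- masks[[1L]]
  wi <- window_index(ref, w)
  if (nrow(wi) < 2L)
    stop("clfi: need at least 2 full windows; grid too small for window ",
         w)
  warea <- w^2 * cell_area_km2(ref)
  rows <- list()
  for (p in names(masks)) {
    stop_if_misaligned(ref, masks[[p]], what = "period masks")
    met <- lapply(seq_len(nrow(wi)), function(i) {
      sub <- window_sub(masks[[p]], wi$wr[i], wi$wc[i], w)
      m <- patch_metrics(sub, window_area_km2 = warea)
      c(np = m$np, pd = m$pd, area_mn = m$area_mn, ai = m$ai,
        any_true = as.integer(m$np > 0))
    })
    df <- cbind(period = p, wi, as.data.frame(do.call(rbind, met)))
    rows[[p]] <- df
  }
  all_df <- do.call(rbind, rows)
  comp <- list(np_norm = minmax01(all_df$np),
               pd_norm = minmax01(all_df$pd),
               area_mn_adjusted = 1 - minmax01(all_df$area_mn),
               ai_adjusted = 1 - minmax01(all_df$ai / 100))
  for (nm in names(comp)) {
    if (all(is.na(comp[[nm]]))) {
      warning("clfi: metric '", nm, "' constant across all windows; ",
              "component fixed at 0.5")
      comp[[nm]] <- rep(0.5, nrow(all_df))
    }
    all_df[[nm]] <- comp[[nm]]
  }
  all_df$clfi <- (all_df$np_norm + all_df$pd_norm +
                    all_df$area_mn_adjusted + all_df$ai_adjusted) / 4
  out <- list()
  for (p in names(masks)) {
    df <- all_df[all_df$period == p, ]
    cg <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    for (i in seq_len(nrow(df))) {
      rowsr <- ((df$wr[i] - 1L) * w + 1L):(df$wr[i] * w)
      colsr <- ((df$wc[i] - 1L) * w + 1L):(df$wc[i] * w)
      cg[rowsr, colsr] <- df$clfi[i]
    }
    out[[p]] <- list(windows = df,
                     clfi_grid = grid(cg, cell_size = ref$cell_size,
                                      origin = ref$origin),
                     mean_clfi = mean(df$clfi[df$any_true == 1]))
  }
  out
}

#' Patch-structure covariates for species distribution models
#'
#' Window-level patch metrics of the natural-habitat (woodland +
#' grassland) mask, painted back to cell resolution so each cell carries
#' its window's NP, PD, AREA_MN and AI as model predictors.
#'
#' @param lu a [landuse_map()].
#' @param window_size_cells square window edge in cells (default 20).
#' @param classes land-use classes forming the habitat mask.
#' @return Named list of [grid()]s: `ehp_np`, `ehp_pd`, `ehp_area_mn`,
#'   `ehp_ai`, aligned with the land-use grid (edge cells beyond the last
#'   full window take the nearest window's values).
#' @export
ehp_covariates <- function(lu, window_size_cells = 20L,
                           classes = c("woodland", "grassland")) {
  mask <- landuse_mask(lu, classes)
  w <- as.integer(window_size_cells)
  g <- mask
  nr <- nrow(g$values); nc <- ncol(g$values)
  nwr <- max(1L, nr %/% w); nwc <- max(1L, nc %/% w)
  warea <- w^2 * cell_area_km2(g)
  arr <- array(NA_real_, c(nwr, nwc, 4L))
  for (wr in seq_len(nwr)) for (wc in seq_len(nwc)) {
    sub <- window_sub(g, wr, wc, w)
    m <- patch_metrics(sub, window_area_km2 = warea)
    arr[wr, wc, ] <- c(m$np, m$pd, m$area_mn, m$ai)
  }
  wr_of <- pmin((seq_len(nr) - 1L) %/% w + 1L, nwr)
  wc_of <- pmin((seq_len(nc) - 1L) %/% w + 1L, nwc)
  nms <- c("ehp_np", "ehp_pd", "ehp_area_mn", "ehp_ai")
  out <- lapply(1:4, function(k)
    grid(arr[wr_of, wc_of, k, drop = TRUE], cell_size = g$cell_size,
         origin = g$origin))
  names(out) <- nms
  # respect the land-use nodata mask
  for (k in seq_along(out)) out[[k]]$values[is.na(lu$grid$values)] <- NA
  out
}
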