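#' Build planning units from grid blocks
#'
#' Aggregates the cell grids into square planning-unit blocks: per-unit
#' cost is the mean of the cost surface (HDI) over the unit's non-nodata
#' cells; feature amounts are exact cell counts of each feature mask
#' times cell area (km2); boundary lengths between orthogonally adjacent
#' units come from shared cell edges, and edges facing nodata or the grid
#' exterior count as outer boundary. Units whose overlap with the reserve
#' mask exceeds `reserve_overlap` are flagged `reserved`; blocks with no
#' usable cells are dropped.
#'
#' @param features named list of 0/1 feature [grid()]s (species
#'   high-suitability, high-value habitat, high-carbon, ...).
#' @param cost cost surface [grid()] (typically from [hdi()]).
#' @param reserves 0/1 [grid()] of existing reserves (NULL = none).
#' @param block_size unit edge in cells (default 10).
#' @param reserve_overlap fraction above which a unit counts as reserved
#'   (default 0.5).
#' @return A `planning_units` object: `units` data.frame (id, cost,
#'   status, n_cells, area_km2), `amounts` (units x features, km2),
#'   `edges` data.frame (id1, id2, length_km), `outer_len` per unit,
#'   `unit_grid` (unit id per cell), `block_size`.
#' @export
build_units <- function(features, cost, reserves = NULL, block_size = 10L,
                        reserve_overlap = 0.5) {
  ref <- cost
  for (f in features) stop_if_misaligned(ref, f, what = "feature grids")
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  b <- as.integer(block_size)
  cell_km <- ref$cell_size / 1000
  blk_r <- (row(ref$values) - 1L) %/% b
  blk_c <- (col(ref$values) - 1L) %/% b
  blk <- blk_r * (max(blk_c) + 1L) + blk_c + 1L
  blk[is.na(ref$values)] <- NA_integer_
  ids_raw <- sort(unique(blk[!is.na(blk)]))
  id_of <- match(blk, ids_raw)              # sequential ids, NA outside
  n <- length(ids_raw)
  U <- matrix(id_of, nr, nc)

  n_cells <- tabulate(U[!is.na(U)], n)
  cost_sum <- rep(0, n)
  cv <- ref$values
  okc <- !is.na(U) & !is.na(cv)
  cost_sum <- unname(tapply(cv[okc], U[okc], sum))
  unit_cost <- cost_sum / n_cells

  amounts <- matrix(0, n, length(features),
                    dimnames = list(NULL, names(features)))
  for (j in seq_along(features)) {
    fv <- features[[j]]$values
    sel <- !is.na(U) & !is.na(fv) & fv > 0
    if (any(sel)) {
      t_ <- tapply(rep(1L, sum(sel)), U[sel], sum)
      amounts[as.integer(names(t_)), j] <- as.numeric(t_) * cell_km^2
    }
  }

  status <- rep("available", n)
  if (!is.null(reserves)) {
    rv <- reserves$values
    selr <- !is.na(U) & !is.na(rv) & rv > 0
    overlap <- rep(0, n)
    if (any(selr)) {
      t_ <- tapply(rep(1L, sum(selr)), U[selr], sum)
      overlap[as.integer(names(t_))] <- as.numeric(t_)
    }
    status[overlap / n_cells > reserve_overlap] <- "reserved"
  }

  # cell-edge accounting: shared vs outer boundary
  pad <- function(m) {
    out <- matrix(NA_integer_, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- m
    out
  }
  P <- pad(U)
  shared <- new.env(parent = emptyenv())
  outer_len <- rep(0, n)
  for (o in list(c(0L, 1L), c(1L, 0L))) {
    a <- P[2:(nr + 1L), 2:(nc + 1L)]
    bn <- P[2:(nr + 1L) + o[1L], 2:(nc + 1L) + o[2L]]
    both <- !is.na(a) & !is.na(bn) & a != bn
    if (any(both)) {
      key <- paste(pmin(a[both], bn[both]), pmax(a[both], bn[both]))
      for (k in seq_along(key)) {
        prev <- if (!is.null(shared[[key[k]]])) shared[[key[k]]] else 0
        shared[[key[k]]] <- prev + cell_km
      }
    }
  }
  # outer: every side of a non-nodata cell facing nodata/exterior
  for (o in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    a <- P[2:(nr + 1L), 2:(nc + 1L)]
    bn <- P[2:(nr + 1L) + o[1L], 2:(nc + 1L) + o[2L]]
    ext <- !is.na(a) & is.na(bn)
    if (any(ext)) {
      t_ <- tapply(rep(cell_km, sum(ext)), a[ext], sum)
      outer_len[as.integer(names(t_))] <-
        outer_len[as.integer(names(t_))] + as.numeric(t_)
    }
  }
  keys <- ls(shared)
  edges <- if (length(keys)) {
    kv <- do.call(rbind, strsplit(keys, " "))
    data.frame(id1 = as.integer(kv[, 1L]), id2 = as.integer(kv[, 2L]),
               length_km = vapply(keys, function(k) shared[[k]], numeric(1)))
  } else data.frame(id1 = integer(0), id2 = integer(0),
                    length_km = numeric(0))
  rownames(edges) <- NULL
  units <- data.frame(id = seq_len(n), cost = unit_cost, status = status,
                      n_cells = n_cells, area_km2 = n_cells * cell_km^2)
  ug <- grid(U, cell_size = ref$cell_size, origin = ref$origin,
             crs = ref$crs)
  structure(list(units = units, amounts = amounts, edges = edges,
                 outer_len = outer_len, unit_grid = ug,
                 block_size = b),
            class = "planning_units")
}

#' Conservation feature targets with penalty scaling
#'
#' Sets per-feature area targets (default 30% of each feature's total
#' extent) and species-penalty factors, and precomputes the shortfall
#' penalty scale: a greedy cost-to-meet-target estimate (cheapest units
#' per unit of feature accumulated until the target is met). The
#' annealer's penalty for feature f is
#' `spf_f * base_f * max(0, (T_f - held_f) / T_f)`.
#'
#' @param pu a `planning_units` object.
#' @param target_fraction fraction of each feature's total amount
#'   (recycled), or use `targets` to set absolute km2.
#' @param spf penalty factor per feature (recycled; default 5).
#' @param targets optional absolute targets (km2), overriding the
#'   fraction.
#' @return A `feature_targets` data.frame: feature, target, spf,
#'   base_penalty, attainable.
#' @export
feature_targets <- function(pu, target_fraction = 0.3, spf = 5,
                            targets = NULL) {
  tot <- colSums(pu$amounts)
  nf <- length(tot)
  tg <- if (is.null(targets)) rep_len(target_fraction, nf) * tot
        else rep_len(targets, nf)
  spf <- rep_len(spf, nf)
  base <- numeric(nf)
  for (f in seq_len(nf)) {
    if (tg[f] <= 0) next
    amt <- pu$amounts[, f]
    has <- which(amt > 0)
    ord <- has[order(pu$units$cost[has] / amt[has])]
    cum <- cumsum(amt[ord])
    need <- which(cum >= tg[f])[1L]
    if (is.na(need)) need <- length(ord)     # unattainable: use all
    base[f] <- sum(pu$units$cost[ord[seq_len(need)]])
  }
  structure(data.frame(feature = colnames(pu$amounts), target = tg,
                       spf = spf, base_penalty = base,
                       attainable = tg <= tot + 1e-9),
            class = c("feature_targets", "data.frame"))
}

#' Simulated-annealing parameters
#'
#' @param blm boundary length modifier (>= 0).
#' @param n_runs repeated runs for selection frequency (default 100).
#' @param iterations annealing iterations per run (default 10000).
#' @param cooling geometric cooling factor in (0, 1) applied per
#'   iteration (default 0.999). The initial temperature is auto-set per
#'   run to the 90th percentile of |delta| over 100 random probe flips.
#' @param init_select_prob probability a free unit starts selected.
#' @param seed RNG seed.
#' @return An `sa_params` list.
#' @export
sa_params <- function(blm = 0, n_runs = 100L, iterations = 10000L,
                      cooling = 0.999, init_select_prob = 0.5, seed = 1L) {
  stopifnot(blm >= 0, cooling > 0, cooling < 1, iterations > 0)
  structure(list(blm = blm, n_runs = as.integer(n_runs),
                 iterations = as.integer(iterations), cooling = cooling,
                 init_select_prob = init_select_prob,
                 seed = as.integer(seed)), class = "sa_params")
}

#' Reserve-selection objective function
#'
#' `value = sum(cost of selected) + blm * exposed boundary + sum_f spf_f *
#' base_f * max(0, (T_f - held_f)/T_f)`. The exposed boundary counts
#' shared edges with exactly one side selected plus outer edges of
#' selected units. Reserved units are forced into the selection.
#'
#' @param selection logical vector over units.
#' @param pu a `planning_units`.
#' @param ft a [feature_targets()].
#' @param blm boundary length modifier.
#' @return list `value`, `cost_term`, `boundary_term`, `boundary_length`,
#'   `penalty_term`, `held`, `selection` (with reserved forced true).
#' @export
objective <- function(selection, pu, ft, blm = 0) {
  sel <- as.logical(selection)
  sel[pu$units$status == "reserved"] <- TRUE
  cost_term <- sum(pu$units$cost[sel])
  bl <- sum(pu$outer_len[sel])
  if (nrow(pu$edges))
    bl <- bl + sum(pu$edges$length_km[xor(sel[pu$edges$id1],
                                          sel[pu$edges$id2])])
  held <- as.numeric(t(pu$amounts) %*% sel)
  shortfall <- ifelse(ft$target > 0,
                      pmax(0, (ft$target - held) / ft$target), 0)
  penalty_term <- sum(ft$spf * ft$base_penalty * shortfall)
  list(value = cost_term + blm * bl + penalty_term,
       cost_term = cost_term, boundary_term = blm * bl,
       boundary_length = bl, penalty_term = penalty_term,
       held = held, selection = sel)
}

#' One simulated-annealing run
#'
#' Starts from a random selection (reserved units forced), proposes
#' single-unit flips accepted when the objective does not worsen or with
#' Boltzmann probability exp(-delta/T), cools geometrically, and
#' finishes with greedy descent to a local optimum. Deterministic for a
#' fixed seed.
#'
#' @param pu a `planning_units`.
#' @param ft a [feature_targets()].
#' @param params an [sa_params()].
#' @param seed RNG seed for this run (default `params$seed`).
#' @return An `sa_solution`: `selection`, objective `value` and its
#'   terms.
#' @export
anneal <- function(pu, ft, params = sa_params(), seed = params$seed) {
  n <- nrow(pu$units)
  if (params$iterations < n)
    warning("anneal: iteration budget below the number of units")
  res <- with_stage_seed(seed, "anneal", {
    .anneal_cpp(pu$units$cost, pu$outer_len,
                as.integer(pu$edges$id1) - 1L,
                as.integer(pu$edges$id2) - 1L,
                pu$edges$length_km, pu$amounts,
                ft$target, ft$spf, ft$base_penalty,
                pu$units$status == "reserved",
                params$blm, params$iterations, params$cooling,
                params$init_select_prob)
  })
  structure(res, class = "sa_solution")
}

#' Selection frequency over repeated annealing runs
#'
#' @param pu a `planning_units`.
#' @param ft a [feature_targets()].
#' @param params an [sa_params()] (`n_runs` runs with derived seeds).
#' @return list `ssoln` (per-unit selection fraction), `best`
#'   (lowest-objective `sa_solution`), `values` (objective per run).
#' @export
ssoln <- function(pu, ft, params = sa_params()) {
  vals <- numeric(params$n_runs)
  freq <- numeric(nrow(pu$units))
  best <- NULL
  for (r in seq_len(params$n_runs)) {
    sol <- anneal(pu, ft, params,
                  seed = stage_seed(params$seed, paste0("ssoln_run_", r)))
    freq <- freq + sol$selection
    vals[r] <- sol$value
    if (is.null(best) || sol$value < best$value) best <- sol
  }
  list(ssoln = freq / params$n_runs, best = best, values = vals)
}

#' BLM sensitivity analysis
#'
#' Runs a short selection-frequency analysis per candidate boundary
#' length modifier and reports the cost vs boundary-length trade-off; the
#' suggested value is the knee of the curve (maximum perpendicular
#' distance to the chord joining the extreme points, on min-max
#' normalised axes).
#'
#' @param pu a `planning_units`.
#' @param ft a [feature_targets()].
#' @param blm_values numeric grid of candidate BLM values (>= 2).
#' @param params an [sa_params()]; `n_runs` here is the short per-BLM
#'   run count (default 10).
#' @return list `curve` data.frame (blm, mean and best-run cost term and
#'   boundary length), `suggested_blm` (knee of the best-run curve).
#' @export
calibrate_blm <- function(pu, ft, blm_values,
                          params = sa_params(n_runs = 10L)) {
  if (length(blm_values) < 2L)
    stop("calibrate_blm: need at least 2 BLM values")
  rows <- lapply(seq_along(blm_values), function(i) {
    p <- params
    p$blm <- blm_values[i]
    p$seed <- stage_seed(params$seed, paste0("blm_", i))
    costs <- bls <- vals <- numeric(p$n_runs)
    for (r in seq_len(p$n_runs)) {
      sol <- anneal(pu, ft, p, seed = stage_seed(p$seed, paste0("r", r)))
      costs[r] <- sol$cost_term
      bls[r] <- sol$boundary_length
      vals[r] <- sol$value
    }
    b <- which.min(vals)
    data.frame(blm = blm_values[i], mean_cost = mean(costs),
               mean_boundary = mean(bls), best_cost = costs[b],
               best_boundary = bls[b])
  })
  curve <- do.call(rbind, rows)
  nx <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v))
                    else (v - min(v)) / diff(range(v))
  x <- nx(curve$best_boundary); y <- nx(curve$best_cost)
  x0 <- x[1L]; y0 <- y[1L]; x1 <- x[length(x)]; y1 <- y[length(y)]
  den <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  d <- if (den == 0) rep(0, length(x))
       else abs((y1 - y0) * x - (x1 - x0) * y + x1 * y0 - y1 * x0) / den
  list(curve = curve, suggested_blm = curve$blm[which.max(d)])
}

#' Extract conservation-gap units from a selection frequency
#'
#' Gaps are the available (non-reserved) units selected in strictly more
#' than `threshold` of the runs.
#'
#' @param sf `ssoln` vector or the list returned by [ssoln()].
#' @param pu a `planning_units`.
#' @param threshold selection-frequency cutoff (default 0.65, strict >).
#' @return Integer vector of gap unit ids.
#' @export
extract_gaps <- function(sf, pu, threshold = 0.65) {
  s <- if (is.list(sf)) sf$ssoln else sf
  pu$units$id[s > threshold & pu$units$status == "available"]
}

#' Write planning-unit tables in the Marxan flat-file dialect
#'
#' Emits pu.csv (id, cost, status), bound.csv (id1, id2, boundary),
#' puvfeat.csv (unit, feature, amount) and targets.csv (feature, target,
#' spf).
#'
#' @param pu a `planning_units`.
#' @param ft a [feature_targets()].
#' @param dir output directory.
#' @export
write_marxan_inputs <- function(pu, ft, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pu$units[, c("id", "cost", "status")],
                   file.path(dir, "pu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id1 = pu$edges$id1, id2 = pu$edges$id2,
                              boundary = pu$edges$length_km),
                   file.path(dir, "bound.csv"), row.names = FALSE)
  long <- data.frame(
    unit = rep(pu$units$id, ncol(pu$amounts)),
    feature = rep(colnames(pu$amounts), each = nrow(pu$amounts)),
    amount = as.vector(pu$amounts))
  utils::write.csv(long[long$amount > 0, ], file.path(dir, "puvfeat.csv"),
                   row.names = FALSE)
  utils::write.csv(ft[, c("feature", "target", "spf")],
                   file.path(dir, "targets.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write planning-unit blocks as GeoJSON rectangles
#'
#' @param pu a `planning_units`.
#' @param ids unit ids to write (e.g. gap units).
#' @param path output `.geojson` path.
#' @param properties optional data.frame of extra per-id properties.
#' @export
write_units_geojson <- function(pu, ids, path, properties = NULL) {
  g <- pu$unit_grid
  cs <- g$cell_size
  feats <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    cells <- which(g$values == id, arr.ind = TRUE)
    r0 <- min(cells[, 1L]) - 1L; r1 <- max(cells[, 1L])
    c0 <- min(cells[, 2L]) - 1L; c1 <- max(cells[, 2L])
    xmin <- g$origin[1] + c0 * cs; xmax <- g$origin[1] + c1 * cs
    ymax <- g$origin[2] - r0 * cs; ymin <- g$origin[2] - r1 * cs
    props <- list(id = id)
    if (!is.null(properties)) props <- c(props, as.list(properties[k, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(list(
           c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
           c(xmin, ymin)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
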