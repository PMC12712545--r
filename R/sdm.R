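#' Extract grid values at point locations
#' @param g a [grid()] or list of grids.
#' @param pts data.frame/matrix with columns `x`, `y`.
#' @return vector (single grid) or matrix (one column per layer).
#' @export
extract_at <- function(g, pts) {
  pts <- as.data.frame(pts)
  if (is_grid(g)) {
    rc <- xy_to_cell(g, pts$x, pts$y)
    return(g$values[cbind(rc[, "row"], rc[, "col"])])
  }
  vapply(g, extract_at, numeric(nrow(pts)), pts = pts)
}

#' Spatially thin occurrence records
#'
#' Removes exact duplicates, then greedily drops randomly chosen points
#' until no two retained records are closer than `radius_km`. The scan
#' order is shuffled under `seed`, so the retained subset is random but
#' reproducible.
#'
#' @param pts data.frame with `x`, `y` (map metres); extra columns kept.
#' @param radius_km minimum separation in km (default 1).
#' @param seed RNG seed for the shuffle.
#' @return Thinned data.frame (row order = retention order).
#' @export
thin_occurrences <- function(pts, radius_km = 1, seed = 1L) {
  stopifnot(radius_km > 0)
  pts <- as.data.frame(pts)
  if (nrow(pts) == 0L) {
    warning("thin_occurrences: empty input")
    return(pts)
  }
  pts <- pts[!duplicated(pts[, c("x", "y")]), , drop = FALSE]
  r_m <- radius_km * 1000
  ord <- with_stage_seed(seed, "thin", sample.int(nrow(pts)))
  pts <- pts[ord, , drop = FALSE]
  keep <- logical(nrow(pts))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    if (!length(kx) ||
        min(sqrt((kx - pts$x[i])^2 + (ky - pts$y[i])^2)) >= r_m) {
      keep[i] <- TRUE
      kx <- c(kx, pts$x[i]); ky <- c(ky, pts$y[i])
    }
  }
  pts[keep, , drop = FALSE]
}

#' Drop highly correlated predictor layers
#'
#' Greedy elimination: while any pair of layers has |Pearson r| (over
#' cells finite in all layers) above `r_max`, the member of the worst pair
#' with the lower univariate importance is dropped. Importance is the
#' absolute point-biserial correlation between layer values and
#' presence/background labels (all non-nodata cells serve as background
#' when none is supplied), so ties in collinearity resolve toward the
#' ecologically more informative layer. Deterministic given inputs.
#'
#' @param layers named list of aligned [grid()]s.
#' @param occurrences data.frame of presence points (`x`, `y`).
#' @param background optional data.frame of background points.
#' @param r_max correlation threshold (default 0.8).
#' @return The retained sublist of `layers`.
#' @export
filter_predictors <- function(layers, occurrences, background = NULL,
                              r_max = 0.8) {
  if (length(layers) < 2L) return(layers)
  mat <- vapply(layers, function(g) as.vector(g$values),
                numeric(length(layers[[1L]]$values)))
  ok <- stats::complete.cases(mat)
  pres_idx <- {
    rc <- xy_to_cell(layers[[1L]], occurrences$x, occurrences$y)
    (rc[, "col"] - 1L) * nrow(layers[[1L]]$values) + rc[, "row"]
  }
  if (is.null(background)) {
    lab <- integer(nrow(mat)); lab[pres_idx] <- 1L
    imp_rows <- which(ok)
    labels <- lab[imp_rows]
    imp_mat <- mat[imp_rows, , drop = FALSE]
  } else {
    bg_rc <- xy_to_cell(layers[[1L]], background$x, background$y)
    bg_idx <- (bg_rc[, "col"] - 1L) * nrow(layers[[1L]]$values) + bg_rc[, "row"]
    rows <- c(pres_idx, bg_idx)
    labels <- rep(c(1L, 0L), c(length(pres_idx), length(bg_idx)))
    imp_mat <- mat[rows, , drop = FALSE]
  }
  importance <- abs(apply(imp_mat, 2L, function(v) {
    if (stats::sd(v) == 0) 0 else stats::cor(v, labels)
  }))
  keep <- names(layers)
  repeat {
    cm <- abs(stats::cor(mat[ok, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[worst]
    drop <- pair[which.min(importance[pair])]
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  layers[keep]
}

#' Sample uniform background (pseudo-absence) points
#'
#' @param g reference [grid()] (non-nodata cells are candidates).
#' @param n number of points (default 500).
#' @param seed RNG seed.
#' @param exclude optional points whose cells are excluded (presences).
#' @return data.frame with `x`, `y` at cell centres.
#' @export
sample_background <- function(g, n = 500L, seed = 1L, exclude = NULL) {
  nr <- nrow(g$values)
  cand <- which(!is.na(as.vector(g$values)))
  if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0) {
    rc <- xy_to_cell(g, exclude$x, exclude$y)
    excl <- (rc[, "col"] - 1L) * nr + rc[, "row"]
    cand <- setdiff(cand, excl)
  }
  if (n > length(cand))
    stop("sample_background: ", n, " requested but only ", length(cand),
         " cells available")
  cells <- with_stage_seed(seed, "background", sample(cand, n))
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cs <- g$cell_size
  data.frame(x = g$origin[1] + (col - 0.5) * cs,
             y = g$origin[2] - (row - 0.5) * cs)
}

#' Surface range envelope (SRE) suitability
#'
#' Cell suitability = fraction of layers whose value falls inside the
#' central presence quantile interval [q, 1-q] (default q = 0.025).
#'
#' @param presence data.frame of training presences (`x`, `y`).
#' @param layers named list of aligned [grid()]s.
#' @param q tail quantile trimmed from each end of the presence range.
#' @return Prediction [grid()] in [0, 1].
#' @export
fit_envelope <- function(presence, layers, q = 0.025) {
  if (nrow(as.data.frame(presence)) < 5L)
    stop("fit_envelope: need at least 5 presence points")
  vals <- extract_at(layers, presence)
  ref <- layers[[1L]]
  score <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (j in seq_along(layers)) {
    rng <- stats::quantile(vals[, j], c(q, 1 - q), na.rm = TRUE, names = FALSE)
    v <- layers[[j]]$values
    score <- score + (v >= rng[1] & v <= rng[2])
  }
  out <- score / length(layers)
  out[is.na(ref$values)] <- NA
  grid(out, cell_size = ref$cell_size, origin = ref$origin, crs = ref$crs)
}

# Design matrix for the ridge logistic learner: standardized layer values
# plus their squares (a linear-link learner needs the quadratic terms to
# represent unimodal niche response).
logistic_features <- function(vals, center, scale) {
  z <- sweep(sweep(vals, 2L, center), 2L, scale, "/")
  cbind(z, z^2)
}

#' Ridge-penalised logistic suitability
#'
#' Logistic regression of presence vs background on standardized layer
#' values and their squares, with an L2 penalty. Deterministic given the
#' training points.
#'
#' @param presence,background data.frames of training points (`x`, `y`).
#' @param layers named list of aligned [grid()]s.
#' @param l2 ridge penalty (glmnet lambda); must be > 0 unless the
#'   classes are linearly separable-free.
#' @return Prediction [grid()] in (0, 1).
#' @export
fit_logistic <- function(presence, background, layers, l2 = 0.01) {
  xp <- extract_at(layers, presence)
  xb <- extract_at(layers, background)
  X <- rbind(xp, xb)
  y <- rep(c(1L, 0L), c(nrow(xp), nrow(xb)))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  F <- logistic_features(X, center, scale)
  if (l2 <= 0) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, F), y,
                                           family = stats::binomial()))
    if (!fit$converged || any(abs(fit$coefficients) > 50, na.rm = TRUE))
      stop("fit_logistic: complete separation; refit with l2 > 0")
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
  } else {
    # fit along a decreasing lambda path ending at l2: glmnet's warm
    # starts make this robust where a cold single-lambda fit can fail to
    # converge on near-separable data
    lam_path <- exp(seq(log(max(100 * l2, 1)), log(l2), length.out = 20))
    fit <- glmnet::glmnet(F, y, family = "binomial", alpha = 0,
                          lambda = lam_path, standardize = FALSE)
    cf <- as.matrix(glmnet::coef.glmnet(fit, s = l2, exact = FALSE))
    beta <- as.numeric(cf)
  }
  ref <- layers[[1L]]
  all_vals <- vapply(layers, function(g) as.vector(g$values),
                     numeric(length(ref$values)))
  ok_cell <- stats::complete.cases(all_vals)
  eta <- rep(NA_real_, nrow(all_vals))
  Fa <- logistic_features(all_vals[ok_cell, , drop = FALSE], center, scale)
  eta[ok_cell] <- beta[1L] + Fa %*% beta[-1L]
  p <- matrix(stats::plogis(eta), nrow(ref$values), ncol(ref$values))
  grid(p, cell_size = ref$cell_size, origin = ref$origin, crs = ref$crs)
}

#' Ingest an externally computed suitability raster as an ensemble member
#'
#' Lets predictions of learners fitted elsewhere (boosting, random forest,
#' MaxEnt, ...) join the TSS-weighted ensemble. The raster must be aligned
#' with the reference grid and lie in [0, 1]; if test data are supplied
#' the evaluation is recomputed internally rather than trusting the claim.
#'
#' @param x path to an ASCII grid or a [grid()].
#' @param model_id identifier used in reports.
#' @param ref reference [grid()] for alignment checking.
#' @param tss_claim optional externally reported TSS.
#' @param test_presence,test_background optional points to recompute the
#'   evaluation.
#' @return An `sdm_member` list (id, prediction, tss, evaluation).
#' @export
load_external_prediction <- function(x, model_id, ref, tss_claim = NULL,
                                     test_presence = NULL,
                                     test_background = NULL) {
  g <- if (is_grid(x)) x else read_grid(x)
  stop_if_misaligned(g, ref, what = "external prediction and reference")
  v <- g$values[!is.na(g$values)]
  if (any(v < 0 | v > 1))
    stop("external prediction '", model_id, "' has values outside [0, 1]")
  ev <- NULL
  tss <- tss_claim
  if (!is.null(test_presence) && !is.null(test_background)) {
    ev <- evaluate(g, test_presence, test_background)
    tss <- ev$tss
  }
  structure(list(id = model_id, prediction = g, tss = tss, evaluation = ev,
                 external = TRUE), class = "sdm_member")
}

#' Evaluate presence/background scores: AUC, TSS, Kappa
#'
#' AUC by the rank (Mann-Whitney) statistic with midranks for ties. TSS =
#' max over thresholds of sensitivity + specificity - 1, sweeping the
#' sorted unique scores ("suitable" means score >= threshold); ties in
#' TSS break toward the lower threshold (the larger predicted suitable
#' area). Kappa is reported at the max-TSS threshold.
#'
#' @param pred a [grid()] of predictions (or use [evaluate_scores()] with
#'   raw score vectors).
#' @param test_presence,test_background data.frames of test points.
#' @return list `auc`, `tss`, `kappa`, `threshold`.
#' @export
evaluate <- function(pred, test_presence, test_background) {
  p <- extract_at(pred, test_presence)
  b <- extract_at(pred, test_background)
  evaluate_scores(p[!is.na(p)], b[!is.na(b)])
}

#' @rdname evaluate
#' @param pres_scores,bg_scores raw predicted scores at test presences and
#'   background points.
#' @export
evaluate_scores <- function(pres_scores, bg_scores) {
  np <- length(pres_scores); nb <- length(bg_scores)
  if (np == 0L || nb == 0L)
    stop("evaluate: empty presence or background test set")
  r <- rank(c(pres_scores, bg_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
  thr <- sort(unique(c(pres_scores, bg_scores)))
  sens <- vapply(thr, function(t) mean(pres_scores >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(bg_scores < t), numeric(1))
  tss <- sens + spec - 1
  best <- which.max(tss)          # which.max -> first (lowest) threshold
  t_star <- thr[best]
  pp <- pres_scores >= t_star; bp <- bg_scores >= t_star
  n <- np + nb
  po <- (sum(pp) + sum(!bp)) / n
  pe <- ((sum(pp) + sum(bp)) * np + (sum(!pp) + sum(!bp)) * nb) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(auc = auc, tss = tss[best], kappa = kappa, threshold = t_star)
}

#' TSS-proportional ensemble weights
#'
#' Members above the inclusion threshold get weights proportional to
#' their TSS, normalised to sum to one; the rest are excluded.
#'
#' @param tss named numeric vector of member TSS values.
#' @param inclusion_threshold minimum TSS for inclusion (default 0.8,
#'   strict >).
#' @return Named weight vector over the included members (sums to 1).
#' @export
ensemble_weights <- function(tss, inclusion_threshold = 0.8) {
  pass <- tss > inclusion_threshold
  if (!any(pass))
    stop("sdm_ensemble: no member exceeds TSS ", inclusion_threshold,
         "; member TSS: ",
         paste(sprintf("%s=%.3f", names(tss), tss), collapse = ", "))
  w <- tss[pass] / sum(tss[pass])
  w
}

#' TSS-weighted ensemble of suitability models
#'
#' For each of `runs` random 75/25 splits of the presences (and
#' background), the internal learners (surface range envelope and ridge
#' logistic) are refitted on the training portion and scored on the
#' held-out portion; external members are rescored per split. A member's
#' TSS is its mean over runs; members above the inclusion threshold
#' (default 0.8) enter the ensemble with weights proportional to TSS
#' (normalised to sum to one). The ensemble surface is the weighted mean
#' of final member predictions, binarised at its own max-TSS threshold;
#' above-threshold cells are graded low/medium/high by natural breaks.
#'
#' @param presence data.frame of (thinned) presences for one species.
#' @param layers named list of predictor [grid()]s.
#' @param external optional list of `sdm_member`s from
#'   [load_external_prediction()].
#' @param members internal learners to fit (`"sre"`, `"logistic"`).
#' @param runs number of train/test resplits (default 10).
#' @param split training fraction (default 0.75).
#' @param inclusion_threshold minimum mean TSS for ensemble membership.
#' @param n_background background points (default 500).
#' @param l2 ridge penalty for the logistic learner.
#' @param seed RNG seed.
#' @return An `sdm_ensemble` object: member table, `weights`, `p_ens`,
#'   `threshold`, `binary`, `classes` (0 unsuitable, 1..3 low/med/high),
#'   `high_mask`, `evaluation` (resubstitution) and `holdout` (mean
#'   held-out AUC/TSS of the weighted ensemble).
#' @export
sdm_ensemble <- function(presence, layers,
                         external = list(),
                         members = c("sre", "logistic"),
                         runs = 10L, split = 0.75,
                         inclusion_threshold = 0.8,
                         n_background = 500L, l2 = 0.01, seed = 1L) {
  presence <- as.data.frame(presence)
  ref <- layers[[1L]]
  background <- sample_background(ref, n = n_background, seed = seed,
                                  exclude = presence)
  fitters <- list(
    sre = function(tp, tb) fit_envelope(tp, layers),
    logistic = function(tp, tb) fit_logistic(tp, tb, layers, l2 = l2))
  fitters <- fitters[members]
  ids <- c(names(fitters), vapply(external, `[[`, character(1), "id"))
  np <- nrow(presence); nb <- nrow(background)
  tss_runs <- auc_runs <- matrix(NA_real_, runs, length(ids),
                                 dimnames = list(NULL, ids))
  hold <- vector("list", runs)
  with_stage_seed(seed, "ensemble", {
    for (r in seq_len(runs)) {
      itr <- sample.int(np, round(split * np))
      ibr <- sample.int(nb, round(split * nb))
      tp <- presence[itr, , drop = FALSE]; vp <- presence[-itr, , drop = FALSE]
      tb <- background[ibr, , drop = FALSE]; vb <- background[-ibr, , drop = FALSE]
      run_scores <- list()
      for (m in names(fitters)) {
        pr <- fitters[[m]](tp, tb)
        sp <- extract_at(pr, vp); sb <- extract_at(pr, vb)
        ev <- evaluate_scores(sp[!is.na(sp)], sb[!is.na(sb)])
        tss_runs[r, m] <- ev$tss; auc_runs[r, m] <- ev$auc
        run_scores[[m]] <- list(p = sp, b = sb)
      }
      for (ex in external) {
        sp <- extract_at(ex$prediction, vp); sb <- extract_at(ex$prediction, vb)
        ev <- evaluate_scores(sp[!is.na(sp)], sb[!is.na(sb)])
        tss_runs[r, ex$id] <- ev$tss; auc_runs[r, ex$id] <- ev$auc
        run_scores[[ex$id]] <- list(p = sp, b = sb)
      }
      hold[[r]] <- run_scores
    }
  })
  mean_tss <- colMeans(tss_runs)
  mean_auc <- colMeans(auc_runs)
  weights <- ensemble_weights(mean_tss, inclusion_threshold)
  sel <- names(weights)
  pass <- ids %in% sel
  final_pred <- list()
  for (m in intersect(sel, names(fitters)))
    final_pred[[m]] <- fitters[[m]](presence, background)
  for (ex in external) if (ex$id %in% sel) final_pred[[ex$id]] <- ex$prediction
  p_ens_v <- 0
  for (m in sel) p_ens_v <- p_ens_v + weights[[m]] * final_pred[[m]]$values
  p_ens <- grid(p_ens_v, cell_size = ref$cell_size, origin = ref$origin,
                crs = ref$crs)
  ev_all <- evaluate(p_ens, presence, background)
  thr <- ev_all$threshold
  binv <- ifelse(is.na(p_ens$values), NA_integer_,
                 as.integer(p_ens$values >= thr))
  binary <- grid(binv, cell_size = ref$cell_size, origin = ref$origin)
  # held-out skill of the weighted ensemble, averaged over the resplits
  hold_ev <- lapply(hold, function(rs) {
    pe <- Reduce(`+`, lapply(sel, function(m) weights[[m]] * rs[[m]]$p))
    be <- Reduce(`+`, lapply(sel, function(m) weights[[m]] * rs[[m]]$b))
    evaluate_scores(pe[!is.na(pe)], be[!is.na(be)])
  })
  holdout <- list(auc = mean(vapply(hold_ev, `[[`, numeric(1), "auc")),
                  tss = mean(vapply(hold_ev, `[[`, numeric(1), "tss")))
  suit_vals <- p_ens$values[!is.na(binv) & binv == 1L]
  kcls <- min(3L, length(unique(suit_vals)))
  clsv <- matrix(NA_integer_, nrow(binv), ncol(binv))
  clsv[!is.na(binv)] <- 0L
  if (kcls >= 1L && length(suit_vals)) {
    brk <- if (kcls == 1L) new_breaks(range(suit_vals), "jenks")
           else jenks_breaks(suit_vals, kcls)
    idx <- findInterval(p_ens$values[which(binv == 1L)], brk$edges,
                        rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L; idx[idx > kcls] <- kcls
    clsv[which(binv == 1L)] <- as.integer(idx)
  }
  classes <- grid(clsv, cell_size = ref$cell_size, origin = ref$origin)
  hm <- ifelse(is.na(clsv), NA_integer_, as.integer(clsv == kcls & kcls > 0))
  high_mask <- grid(hm, cell_size = ref$cell_size, origin = ref$origin)
  structure(list(
    members = data.frame(id = ids, tss = as.numeric(mean_tss),
                         auc = as.numeric(mean_auc), included = pass),
    weights = weights, p_ens = p_ens, threshold = thr,
    member_predictions = final_pred,
    binary = binary, classes = classes, high_mask = high_mask,
    evaluation = ev_all, holdout = holdout, n_suit_classes = kcls,
    background = background), class = "sdm_ensemble")
}

#' Stack per-species high-suitability masks into a richness surface
#'
#' Richness = number of species whose high-suitability class covers the
#' cell, graded with fixed bins: none (0), low (1-2), moderate (3-4),
#' relatively high (5-6), high (>= 7).
#'
#' @param surfaces list of `sdm_ensemble` objects (or 0/1 high-mask
#'   grids).
#' @return list `richness` grid, `classes` grid (0..4), `labels`.
#' @export
stack_richness <- function(surfaces) {
  masks <- lapply(surfaces, function(s)
    if (is_grid(s)) s else s$high_mask)
  ref <- masks[[1L]]
  for (m in masks) stop_if_misaligned(ref, m, what = "high-suitability masks")
  rich <- Reduce(`+`, lapply(masks, function(m) {
    v <- m$values; v[is.na(v)] <- 0L; v
  }))
  rich[is.na(ref$values) & Reduce(`&`, lapply(masks, function(m) is.na(m$values)))] <- NA
  edges <- c(0, 1, 3, 5, 7, Inf)
  cls <- matrix(findInterval(rich, edges) - 1L, nrow(rich), ncol(rich))
  labels <- c("none", "low", "moderate", "relatively_high", "high")
  list(richness = grid(rich, cell_size = ref$cell_size, origin = ref$origin),
       classes = grid(cls, cell_size = ref$cell_size, origin = ref$origin),
       labels = labels)
}
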