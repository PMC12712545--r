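test_that("spatial thinning enforces the minimum separation", {
  two <- data.frame(x = c(500, 500), y = c(500, 500))
  expect_equal(nrow(thin_occurrences(two, 1, seed = 1)), 1L)

  far <- data.frame(x = c(0, 5000), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(far, 1, seed = 1)), 2L)

  set.seed(8)
  pts <- data.frame(x = runif(100, 0, 3000), y = runif(100, 0, 3000))
  th <- thin_occurrences(pts, 1, seed = 4)
  d <- as.matrix(dist(th[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 1000)
  # seed-reproducible
  expect_identical(th, thin_occurrences(pts, 1, seed = 4))
  expect_warning(thin_occurrences(pts[0, ], 1), "empty")
})

test_that("predictor filtering drops collinear layers by importance", {
  set.seed(21)
  a <- grid(matrix(rnorm(900), 30, 30))
  b <- grid(matrix(rnorm(900), 30, 30))
  occ <- data.frame(x = runif(20, 0, 30000), y = runif(20, 0, 30000))

  # identical copy: one of the pair dropped
  kept <- filter_predictors(list(a = a, a2 = a, b = b), occ)
  expect_length(kept, 2L)
  expect_true("b" %in% names(kept))

  # sign-flipped copy (r = -1): |r| is what counts
  neg <- a; neg$values <- -neg$values
  kept2 <- filter_predictors(list(a = a, neg = neg, b = b), occ)
  expect_length(kept2, 2L)

  # independent noise: nothing dropped
  kept3 <- filter_predictors(list(a = a, b = b), occ, r_max = 0.8)
  expect_length(kept3, 2L)
  expect_lt(abs(cor(as.vector(a$values), as.vector(b$values))), 0.8)

  # single layer returned unchanged
  expect_length(filter_predictors(list(a = a), occ), 1L)
})

test_that("background sampling is uniform, seeded and exclusion-aware", {
  g <- grid(matrix(0, 50, 50))
  b1 <- sample_background(g, 500, seed = 9)
  expect_identical(b1, sample_background(g, 500, seed = 9))
  expect_error(sample_background(g, 3000, seed = 1), "only")

  # exclude all but 5 cells -> exactly those 5
  g5 <- grid(matrix(0, 2, 5))
  cc <- cell_centers(g5)
  all_pts <- expand.grid(x = cc$x, y = cc$y)
  excl <- all_pts[-(1:5), ]
  got <- sample_background(g5, 5, seed = 2, exclude = excl)
  expect_setequal(paste(got$x, got$y),
                  paste(all_pts$x[1:5], all_pts$y[1:5]))

  # aggregate draws are uniform (chi-square, alpha = 0.01)
  counts <- matrix(0, 50, 50)
  for (s in 1:20) {
    bs <- sample_background(g, 500, seed = s)
    rc <- xy_to_cell(g, bs$x, bs$y)
    for (i in seq_len(nrow(rc))) counts[rc[i, 1], rc[i, 2]] <-
        counts[rc[i, 1], rc[i, 2]] + 1
  }
  block <- tapply(as.vector(counts),
                  list((row(counts) - 1) %/% 10, (col(counts) - 1) %/% 10),
                  sum)
  expect_gt(chisq.test(as.vector(block))$p.value, 0.01)
})

test_that("the surface range envelope scores by quantile membership", {
  set.seed(3)
  layers <- list(a = grid(matrix(rnorm(400), 20, 20)),
                 b = grid(matrix(rnorm(400), 20, 20)),
                 c = grid(matrix(rnorm(400), 20, 20)))
  pres <- data.frame(x = runif(30, 0, 20000), y = runif(30, 0, 20000))
  pr <- fit_envelope(pres, layers)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_true(all(pr$values %in% c(0, 1/3, 2/3, 1)))

  vals <- extract_at(layers, pres)
  qs <- apply(vals, 2, quantile, c(0.025, 0.975))
  # find cells inside all envelopes and cells failing exactly one
  inside <- sapply(seq_along(layers), function(j) {
    v <- as.vector(layers[[j]]$values); v >= qs[1, j] & v <= qs[2, j]
  })
  n_in <- rowSums(inside)
  expect_equal(as.vector(pr$values)[n_in == 3][1], 1)
  if (any(n_in == 2)) expect_equal(as.vector(pr$values)[n_in == 2][1], 2/3)
  if (any(n_in == 0)) expect_equal(as.vector(pr$values)[n_in == 0][1], 0)

  expect_error(fit_envelope(pres[1:4, ], layers), "at least 5")
})

test_that("ridge logistic discriminates informative niches and degrades to prevalence", {
  set.seed(14)
  informative <- grid(matrix(seq(-2, 2, length.out = 900), 30, 30))
  layers <- list(a = informative)
  # presences where layer is high, background uniform
  cells_hi <- which(informative$values > 1)
  cells_lo <- which(informative$values < 0.5)
  cc <- cell_centers(informative)
  rc <- arrayInd(sample(cells_hi, 30), dim(informative$values))
  pres <- data.frame(x = cc$x[rc[, 2]], y = cc$y[rc[, 1]])
  rb <- arrayInd(sample(cells_lo, 200), dim(informative$values))
  bg <- data.frame(x = cc$x[rb[, 2]], y = cc$y[rb[, 1]])
  pr <- fit_logistic(pres, bg, layers)
  expect_gt(evaluate(pr, pres, bg)$auc, 0.95)

  # shuffled labels: AUC ~ 0.5 across seeds
  aucs <- sapply(1:20, function(s) {
    set.seed(s)
    n <- nrow(pres)
    pool <- rbind(pres, bg)
    idx <- sample(nrow(pool), n)
    p2 <- pool[idx, ]; b2 <- pool[-idx, ]
    evaluate(fit_logistic(p2, b2, layers), p2, b2)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.07)

  # heavy shrinkage: predictions approach a constant
  pr_l2 <- fit_logistic(pres, bg, layers, l2 = 1e6)
  expect_lt(diff(range(pr_l2$values)), 0.02)
})

test_that("evaluation metrics match exhaustive rank and threshold enumeration", {
  perfect <- evaluate_scores(c(0.9, 0.8), c(0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tss, 1)
  expect_equal(perfect$kappa, 1)

  flat <- evaluate_scores(rep(0.4, 5), rep(0.4, 7))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$tss, 0)

  p <- c(0.9, 0.8, 0.6); b <- c(0.7, 0.3, 0.2)
  ev <- evaluate_scores(p, b)
  # rank-pair oracle
  pairs <- outer(p, b, function(x, y) (x > y) + 0.5 * (x == y))
  expect_equal(ev$auc, mean(pairs))
  expect_equal(ev$auc, 8 / 9)
  # exhaustive threshold sweep oracle
  tss_all <- sapply(sort(unique(c(p, b))), function(t)
    mean(p >= t) + mean(b < t) - 1)
  expect_equal(ev$tss, max(tss_all))
  expect_equal(ev$tss, 2 / 3)
  # the stored threshold attains the maximum
  expect_equal(mean(p >= ev$threshold) + mean(b < ev$threshold) - 1, ev$tss)

  # AUC invariant under strictly monotone transforms
  ev2 <- evaluate_scores(exp(3 * p), exp(3 * b))
  expect_equal(ev2$auc, ev$auc)

  expect_error(evaluate_scores(numeric(0), b), "empty")
})

test_that("external predictions are validated before joining the ensemble", {
  ref <- grid(matrix(0.5, 10, 10))
  ok <- load_external_prediction(grid(matrix(0.5, 10, 10)), "ext", ref)
  expect_s3_class(ok, "sdm_member")
  expect_error(load_external_prediction(grid(matrix(1.2, 10, 10)), "bad", ref),
               "outside")
  expect_error(load_external_prediction(grid(matrix(0.5, 9, 10)), "mis", ref),
               "not aligned")
})

test_that("the TSS-weighted ensemble honours its weight and convexity contracts", {
  w <- ensemble_weights(c(a = 0.9, b = 0.85))
  expect_equal(unname(w), c(18 / 35, 17 / 35), tolerance = 1e-15)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(ensemble_weights(c(a = 0.5, b = 0.7)), "no member exceeds")
  set.seed(10)
  for (i in 1:20) {
    tss <- runif(sample(2:6, 1), 0.801, 1)
    names(tss) <- paste0("m", seq_along(tss))
    expect_equal(sum(ensemble_weights(tss)), 1, tolerance = 1e-12)
  }

  sc <- landscape_scenario(seed = 2, shape = c(60L, 60L), n_species = 1L)
  env <- make_environment(sc)
  occ <- make_occurrences(sc, env)
  ens <- sdm_ensemble(occ, env, runs = 5L, n_background = 200L, seed = 2)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)

  # convexity: ensemble surface bounded by member predictions cell-wise
  mp <- sapply(ens$member_predictions, function(g) as.vector(g$values))
  pe <- as.vector(ens$p_ens$values)
  okc <- !is.na(pe)
  expect_true(all(pe[okc] >= apply(mp, 1, min)[okc] - 1e-12))
  expect_true(all(pe[okc] <= apply(mp, 1, max)[okc] + 1e-12))

  # single qualifying member -> ensemble is that member with weight 1
  if (length(ens$weights) == 1L)
    expect_equal(pe, as.vector(ens$member_predictions[[1]]$values))

  # binarisation reproducibility: re-evaluating on the stored points
  # returns the stored threshold
  ev <- evaluate(ens$p_ens, occ, ens$background)
  expect_equal(ev$threshold, ens$threshold)
  bin <- as.vector(ens$binary$values)
  expect_equal(bin[okc], as.integer(pe[okc] >= ens$threshold))
})

test_that("richness stacking counts high-suitability masks with fixed bins", {
  mk <- function(v) grid(matrix(v, 4, 4))
  ten <- replicate(10, mk(1), simplify = FALSE)
  st <- stack_richness(ten)
  expect_true(all(st$richness$values == 10))
  expect_true(all(st$classes$values == 4L))   # "high" (>= 7)

  none <- stack_richness(list(mk(0), mk(0)))
  expect_true(all(none$classes$values == 0L))

  set.seed(6)
  masks <- replicate(7, mk(rbinom(16, 1, 0.5)), simplify = FALSE)
  st2 <- stack_richness(masks)
  brute <- Reduce(`+`, lapply(masks, `[[`, "values"))
  expect_equal(st2$richness$values, brute)
  bins <- cut(as.vector(brute), c(-1, 0.5, 2.5, 4.5, 6.5, Inf),
              labels = FALSE) - 1L
  expect_equal(as.vector(st2$classes$values), bins)
})
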