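sc40 <- landscape_scenario(seed = 11, shape = c(40L, 40L))

test_that("environment surfaces are deterministic, smooth and standardized", {
  e1 <- make_environment(sc40)
  e2 <- make_environment(sc40)
  expect_identical(e1, e2)
  expect_named(e1, c("elevation", "moisture", "temperature"))
  for (g in e1) {
    v <- g$values
    expect_lt(abs(mean(v)), 1e-6)
    expect_equal(sd(v), 1, tolerance = 1e-9)
    lag1 <- cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
    expect_gt(lag1, 0.5)
  }
  expect_error(make_environment(landscape_scenario(shape = c(10L, 40L))),
               "20 x 20")
})

test_that("land-use series follows the Markov transition matrix", {
  env <- make_environment(sc40)

  ident <- diag(6)
  dimnames(ident) <- dimnames(default_markov_matrix())
  sc_i <- landscape_scenario(seed = 11, shape = c(40L, 40L),
                             markov_matrix = ident)
  lus <- make_landuse_series(sc_i, env)
  expect_identical(lus[[1]]$grid$values, lus[[2]]$grid$values)
  expect_identical(lus[[1]]$grid$values, lus[[3]]$grid$values)

  to_crop <- matrix(0, 6, 6); to_crop[, 1] <- 1
  dimnames(to_crop) <- dimnames(default_markov_matrix())
  sc_c <- landscape_scenario(seed = 11, shape = c(40L, 40L),
                             markov_matrix = to_crop)
  lus_c <- make_landuse_series(sc_c, env)
  expect_true(all(lus_c[[2]]$grid$values == landuse_legend()[["cropland"]]))

  bad <- default_markov_matrix(); bad[1, 1] <- 0.5
  expect_error(landscape_scenario(markov_matrix = bad), "summing to 1")

  # empirical transition frequencies on a large grid
  sc_big <- landscape_scenario(seed = 5, shape = c(200L, 200L),
                               periods = c("t0", "t1"))
  env_big <- make_environment(sc_big)
  lus_big <- make_landuse_series(sc_big, env_big)
  prev <- lus_big[[1]]$grid$values
  nxt <- lus_big[[2]]$grid$values
  m <- sc_big$markov_matrix
  for (cls in 1:6) {
    idx <- prev == cls
    if (sum(idx) < 100) next
    emp <- tabulate(nxt[idx], 6) / sum(idx)
    expect_true(all(abs(emp - m[cls, ]) <= 0.02),
                info = paste("class", cls))
  }
})

test_that("occurrences are seeded, niche-concentrated, and uniform in the broad-niche limit", {
  env <- make_environment(sc40)
  o1 <- make_occurrences(sc40, env)
  o2 <- make_occurrences(sc40, env)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), sc40$n_species * sc40$n_occurrences)

  # sampled cells sit closer to the optimum than the landscape average
  for (s in seq_len(sc40$n_species)) {
    pts <- o1[o1$species == sprintf("species_%02d", s), ]
    ev <- extract_at(env$elevation, pts)
    opt <- sc40$niche_optima[s, 1]
    expect_lt(abs(mean(ev) - opt), abs(mean(env$elevation$values) - opt))
  }

  # breadth -> infinity: uniform over the grid (chi-square, alpha = 0.01)
  sc_u <- landscape_scenario(seed = 3, shape = c(60L, 60L), n_species = 1L,
                             niche_breadth = 1e6, n_occurrences = 1000L,
                             jitter_occurrences = FALSE)
  env_u <- make_environment(sc_u)
  pts <- make_occurrences(sc_u, env_u)
  rc <- xy_to_cell(env_u[[1]], pts$x, pts$y)
  block <- (rc[, "row"] - 1) %/% 20 * 3 + (rc[, "col"] - 1) %/% 20 + 1
  obs <- tabulate(block, 9)
  p <- chisq.test(obs)$p.value
  expect_gt(p, 0.01)

  sc_small <- landscape_scenario(seed = 3, shape = c(20L, 20L),
                                 n_species = 1L, n_occurrences = 500L)
  env_s <- make_environment(sc_small)
  expect_error(make_occurrences(sc_small, env_s, n = 500L), "positive probability")
})

test_that("ancillary surfaces have the advertised structure", {
  env <- make_environment(sc40)
  lus <- make_landuse_series(sc40, env)
  anc <- make_ancillary(sc40, lus[[1]])

  # GDP tracks smoothed construction density
  constr <- landuse_mask(lus[[1]], "construction")$values
  dens <- gapscape:::box_blur(constr, r = 3L, passes = 2L)
  expect_gte(cor(as.vector(anc$gdp$values), as.vector(dens)),
             sc40$gdp_coupling)

  # reserves cover the requested fraction
  frac <- mean(anc$reserves$values)
  expect_lt(abs(frac - sc40$reserve_fraction), 0.02)
  sc0 <- landscape_scenario(seed = 11, shape = c(40L, 40L),
                            reserve_fraction = 0)
  anc0 <- make_ancillary(sc0, lus[[1]])
  expect_equal(sum(anc0$reserves$values), 0)

  # road: one cell per column, queen-connected single component
  road <- anc$threats$road$values
  expect_true(all(colSums(road) == 1))
  expect_equal(label_patches(anc$threats$road)$np, 1L)

  # determinism
  expect_identical(anc, make_ancillary(sc40, lus[[1]]))
})

test_that("a full scenario writes to disk and reads back consistently", {
  dir <- withr::local_tempdir()
  sc <- landscape_scenario(seed = 2, shape = c(30L, 30L),
                           periods = c("t0", "t1"))
  gen <- write_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "scenario.yaml")))
  expect_true(file.exists(file.path(dir, "occurrences.csv")))
  g <- read_grid(file.path(dir, "env_elevation.asc"))
  expect_equal(g$values, gen$environment$elevation$values, tolerance = 1e-12)
  lu <- read_grid(file.path(dir, "landuse_t0.asc"))
  expect_identical(lu$values, gen$landuse$t0$grid$values)
})
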