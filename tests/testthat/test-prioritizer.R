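test_that("grid-block planning units carry exact geometry and amounts", {
  hdi_g <- grid(matrix(c(0.1, 0.1, 0.9, 0.9,
                         0.1, 0.1, 0.9, 0.9,
                         0.5, 0.5, 0.2, 0.2,
                         0.5, 0.5, 0.2, 0.2), 4, 4))
  feat <- grid(matrix(c(rep(1, 4), rep(0, 12)), 4, 4))
  pu <- build_units(list(f1 = feat), hdi_g, block_size = 2L)

  expect_equal(nrow(pu$units), 4L)
  # every orthogonal neighbour pair shares 2 km of boundary
  expect_equal(nrow(pu$edges), 4L)
  expect_true(all(pu$edges$length_km == 2))
  expect_true(all(pu$outer_len == 4))
  # column 1 of the feature splits between the two left units
  expect_equal(sum(pu$amounts), 4)     # conservation: total feature area
  expect_equal(sort(pu$amounts[pu$amounts > 0]), c(2, 2))

  # a feature covering one unit fully
  f2 <- grid(matrix(0, 4, 4)); f2$values[1:2, 1:2] <- 1
  pu2 <- build_units(list(f2 = f2), hdi_g, block_size = 2L)
  expect_equal(as.vector(pu2$amounts), c(4, 0, 0, 0))

  # reserve overlap > 50% flags the unit reserved
  res <- grid(matrix(0, 4, 4)); res$values[1:2, 1:2] <- 1
  pu3 <- build_units(list(f2 = f2), hdi_g, reserves = res, block_size = 2L)
  expect_equal(pu3$units$status, c("reserved", rep("available", 3)))
})

test_that("the objective decomposes into cost, boundary and penalty terms", {
  inst <- random_instance(4, 2, seed = 1)
  pu <- inst$pu; ft <- inst$ft

  # empty selection: value = sum of spf * base_penalty
  o0 <- objective(rep(FALSE, 4), pu, ft, blm = 0.5)
  expect_equal(o0$cost_term, 0)
  expect_equal(o0$penalty_term, sum(ft$spf * ft$base_penalty))
  expect_equal(o0$value, o0$penalty_term + 0.5 * o0$boundary_length)

  # all selected: penalty exactly 0, boundary = outer perimeter
  o1 <- objective(rep(TRUE, 4), pu, ft, blm = 0.5)
  expect_equal(o1$penalty_term, 0)
  expect_equal(o1$boundary_length, sum(pu$outer_len))
  expect_equal(o1$value,
               sum(pu$units$cost) + 0.5 * sum(pu$outer_len))

  # hand arithmetic on three enumerated selections
  for (sel in list(c(TRUE, FALSE, FALSE, TRUE),
                   c(FALSE, TRUE, TRUE, FALSE),
                   c(TRUE, TRUE, FALSE, FALSE))) {
    o <- objective(sel, pu, ft, blm = 0.3)
    cost <- sum(pu$units$cost[sel])
    bl <- sum(pu$outer_len[sel])
    for (e in seq_len(nrow(pu$edges)))
      if (xor(sel[pu$edges$id1[e]], sel[pu$edges$id2[e]]))
        bl <- bl + pu$edges$length_km[e]
    held <- colSums(pu$amounts * sel)
    pen <- sum(ft$spf * ft$base_penalty *
                 pmax(0, (ft$target - held) / ft$target))
    expect_equal(o$value, cost + 0.3 * bl + pen, tolerance = 1e-12)
    expect_gte(o$cost_term, 0)
    expect_gte(o$boundary_term, 0)
    expect_gte(o$penalty_term, 0)
  }
})

test_that("annealing finds the cheap covering unit and respects reservations", {
  # one feature coverable by one cheap unit, blm = 0
  units <- data.frame(id = 1:5, cost = c(0.2, 0.9, 0.8, 0.7, 0.6),
                      status = "available")
  amounts <- matrix(c(5, 0, 0, 0, 0), 5, 1,
                    dimnames = list(NULL, "f"))
  pu <- structure(list(units = units, amounts = amounts,
                       edges = data.frame(id1 = integer(0),
                                          id2 = integer(0),
                                          length_km = numeric(0)),
                       outer_len = rep(1, 5)),
                  class = "planning_units")
  ft <- feature_targets(pu, targets = 4)
  sol <- anneal(pu, ft, sa_params(iterations = 500), seed = 3)
  expect_equal(sol$selection, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # exhaustive check: no single-unit solution beats it
  enum <- enumerate_optimum(pu, ft, 0)
  expect_equal(sol$value, enum$value, tolerance = 1e-12)

  # reserved units are always selected
  units$status[2] <- "reserved"
  pu$units <- units
  sol2 <- anneal(pu, ft, sa_params(iterations = 500), seed = 3)
  expect_true(sol2$selection[2])
  expect_identical(anneal(pu, ft, sa_params(iterations = 500), seed = 3),
                   sol2)   # seed determinism
})

test_that("annealed objectives track the exhaustive optimum on small instances", {
  ok <- 0L; n_inst <- 25L
  for (i in seq_len(n_inst)) {
    inst <- random_instance(sample(6:12, 1), sample(2:3, 1), seed = 100 + i,
                            reserve_one = i %% 3 == 0)
    enum <- enumerate_optimum(inst$pu, inst$ft, blm = 0.1)
    best <- min(sapply(1:10, function(s)
      anneal(inst$pu, inst$ft,
             sa_params(blm = 0.1, iterations = 400, cooling = 0.99),
             seed = s)$value))
    if (best <= enum$value * 1.02 + 1e-9) ok <- ok + 1L
  }
  expect_gte(ok, ceiling(0.95 * n_inst))
})

test_that("selection frequency separates irreplaceable from useless units", {
  # unit 1 irreplaceable (only holder of the feature), unit 4 useless
  units <- data.frame(id = 1:4, cost = c(0.5, 0.3, 0.3, 0.4),
                      status = "available")
  amounts <- matrix(c(3, 0.2, 0.2, 0), 4, 1, dimnames = list(NULL, "f"))
  pu <- structure(list(units = units, amounts = amounts,
                       edges = data.frame(id1 = integer(0),
                                          id2 = integer(0),
                                          length_km = numeric(0)),
                       outer_len = rep(1, 4)),
                  class = "planning_units")
  ft <- feature_targets(pu, targets = 2.5)
  sf <- ssoln(pu, ft, sa_params(n_runs = 30, iterations = 400, seed = 7))
  expect_true(all(sf$ssoln >= 0 & sf$ssoln <= 1))
  expect_equal(sf$ssoln[1], 1)
  expect_lt(sf$ssoln[4], 0.2)

  # reserved units have ssoln 1 by construction
  pu$units$status[4] <- "reserved"
  sf2 <- ssoln(pu, ft, sa_params(n_runs = 10, iterations = 200, seed = 7))
  expect_equal(sf2$ssoln[4], 1)

  # gap extraction: strict threshold, reserved excluded
  s <- c(0.66, 0.65, 0.9, 1)
  expect_equal(extract_gaps(s, pu, 0.65), c(1L, 3L))
})

test_that("BLM calibration reports the cost-boundary trade-off", {
  inst <- random_instance(12, 2, seed = 42)
  inst$ft$spf <- 30      # targets binding at every tested BLM
  grid_blm <- c(0, 0.05, 0.2, 1)
  cal <- calibrate_blm(inst$pu, inst$ft, grid_blm,
                       sa_params(n_runs = 10, iterations = 400, seed = 5))
  expect_equal(nrow(cal$curve), 4L)
  expect_true(cal$suggested_blm %in% grid_blm)
  # no boundary pressure spends the least on cost in the best run
  expect_equal(which.min(cal$curve$best_cost), 1L)
  # boundary pressure shortens the selected set's boundary
  expect_lt(cal$curve$best_boundary[4], cal$curve$best_boundary[1])
  expect_true(all(diff(cal$curve$mean_boundary) <= 1e-9) ||
                cal$curve$mean_boundary[4] < cal$curve$mean_boundary[1])
  expect_error(calibrate_blm(inst$pu, inst$ft, 0.1), "at least 2")
})

test_that("Marxan-dialect tables and GeoJSON round out the outputs", {
  hdi_g <- grid(matrix(runif(64), 8, 8))
  feat <- grid(matrix(rbinom(64, 1, 0.4), 8, 8))
  pu <- build_units(list(f1 = feat), hdi_g, block_size = 4L)
  ft <- feature_targets(pu)
  dir <- withr::local_tempdir()
  write_marxan_inputs(pu, ft, dir)
  expect_true(all(file.exists(file.path(dir, c("pu.csv", "bound.csv",
                                               "puvfeat.csv",
                                               "targets.csv")))))
  pv <- read.csv(file.path(dir, "puvfeat.csv"))
  expect_equal(sum(pv$amount), sum(pu$amounts))

  gj <- file.path(dir, "units.geojson")
  write_units_geojson(pu, pu$units$id[1:2], gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2L)
})
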