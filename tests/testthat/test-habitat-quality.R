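# single-class land-use helper
uniform_lu <- function(class, nr = 3, nc = 3) {
  landuse_map(gridm(landuse_legend()[[class]], nr, nc))
}

test_that("threat impact follows the distance-decay definition", {
  src <- gridm(0, 11, 11); src$values[6, 6] <- 1
  th <- threat_spec("t", 1, 3, "linear", src)
  imp <- threat_impact(th)$values
  expect_equal(imp[6, 6], 1)               # distance 0
  expect_equal(imp[6, 9], 0)               # distance d_max
  expect_equal(imp[6, 10], 0)              # beyond d_max
  # brute-force per-cell enumeration
  for (i in 1:11) for (j in 1:11) {
    d <- sqrt((i - 6)^2 + (j - 6)^2)
    expected <- if (d <= 3) 1 - d / 3 else 0
    expect_equal(imp[i, j], expected, tolerance = 1e-12)
  }
  # exponential decay reaches ~0.05 at d_max
  the <- threat_spec("t", 1, 3, "exponential", src)
  impe <- threat_impact(the)$values
  expect_equal(impe[6, 9], exp(-2.99), tolerance = 1e-12)
  # empty source
  expect_warning(z <- threat_impact(threat_spec("t", 1, 3, "linear",
                                                gridm(0, 5, 5))),
                 "empty source")
  expect_true(all(z$values == 0))
})

test_that("degradation is the normalised threat-weighted sensitivity sum", {
  lu <- uniform_lu("woodland")
  hab <- c(cropland = 0.3, woodland = 1, grassland = 0.8, water = 0.9,
           construction = 0, unused = 0.1)

  # all sensitivities zero -> D == 0
  s0 <- matrix(0, 6, 2, dimnames = list(names(hab), c("a", "b")))
  src <- gridm(1, 3, 3)
  th <- list(threat_spec("a", 1, 2, "linear", src),
             threat_spec("b", 2, 2, "linear", src))
  D0 <- degradation(th, sensitivity_table(hab, s0), lu)
  expect_true(all(D0$values == 0))

  # one threat, w = 1, S = 0.5, impact 0.8 -> D = 0.4
  s1 <- matrix(0.5, 6, 1, dimnames = list(names(hab), "a"))
  src08 <- gridm(0, 3, 3); src08$values[2, 2] <- 0.8
  D1 <- degradation(list(threat_spec("a", 1, 0.5, "linear", src08)),
                    sensitivity_table(hab, s1), lu)
  expect_equal(D1$values[2, 2], 0.4, tolerance = 1e-12)

  # two threats with weights {3, 1}: hand-computed weighted sum
  sa <- matrix(c(0.6, 0.2), 6, 2, byrow = TRUE,
               dimnames = list(names(hab), c("a", "b")))
  sa[] <- rep(c(0.6, 0.2), each = 6)
  srcA <- gridm(1, 3, 3); srcB <- gridm(0.5, 3, 3)
  thr <- list(threat_spec("a", 3, 10, "linear", srcA),
              threat_spec("b", 1, 10, "linear", srcB))
  D2 <- degradation(thr, sensitivity_table(hab, sa), lu)
  impA <- threat_impact(thr[[1]])$values
  impB <- threat_impact(thr[[2]])$values
  manual <- (3 / 4) * impA * 0.6 + (1 / 4) * impB * 0.2
  expect_equal(D2$values, manual, tolerance = 1e-12)

  # doubling all weights leaves D unchanged (weights normalised)
  thr2 <- list(threat_spec("a", 6, 10, "linear", srcA),
               threat_spec("b", 2, 10, "linear", srcB))
  expect_equal(degradation(thr2, sensitivity_table(hab, sa), lu)$values,
               D2$values, tolerance = 1e-14)

  expect_error(degradation(list(threat_spec("a", 0, 1, "linear", src)),
                           sensitivity_table(hab, s1), lu),
               "total threat weight")
})

test_that("quality follows the half-saturation closed forms", {
  lu <- uniform_lu("woodland")        # H = 1
  sens <- default_sensitivity()

  # D = 0 everywhere -> Q = H exactly (k falls back with warning)
  D0 <- gridm(0, 3, 3)
  expect_warning(q0 <- hq_quality(D0, lu, sens), "k set to 0.5")
  expect_equal(q0$quality$values, matrix(1, 3, 3), tolerance = 1e-15)

  # fixed k: D = k -> Q = H/2; D = 2k -> closed form
  Dk <- gridm(c(0.2, 0.4, rep(0, 7)), 3, 3)
  qk <- hq_quality(Dk, lu, sens, z = 2.5, k = 0.2)
  expect_equal(qk$quality$values[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(qk$quality$values[2, 1], 1 - 2^2.5 / (2^2.5 + 1),
               tolerance = 1e-12)

  # k = auto is max(D)/2, so the most degraded cell is at D = 2k
  qa <- hq_quality(Dk, lu, sens)
  expect_equal(qa$k, 0.2)
  expect_equal(qa$quality$values[2, 1], 1 - 2^2.5 / (2^2.5 + 1),
               tolerance = 1e-12)

  # monotonicity: Q strictly decreasing in D for H > 0; 0 <= Q <= H
  dd <- seq(0, 1, length.out = 50)
  qd <- hq_quality(gridm(dd, 5, 10), uniform_lu("grassland", 5, 10), sens,
                   k = 0.3)
  qv <- as.vector(qd$quality$values)[order(dd)]
  expect_true(all(diff(qv[order(sort(dd))]) <= 0))
  expect_true(all(qv >= 0 & qv <= 0.8 + 1e-15))
})

test_that("quality classes and the high-value mask follow the five levels", {
  lu <- uniform_lu("woodland", 1, 5)
  sens <- default_sensitivity()
  # engineered degradation giving quality 1, .7, .5, .3, .1 at k=0.2, z=2.5
  q_target <- c(0.99, 0.7, 0.5, 0.3, 0.1)
  d_for <- function(q) 0.2 * ((1 - q) / q)^(1 / 2.5)
  D <- gridm(d_for(q_target), 1, 5)
  r <- hq_quality(D, lu, sens, k = 0.2)
  expect_equal(as.vector(r$classes$values), c(5L, 4L, 3L, 2L, 1L))
  expect_equal(as.vector(r$high_value_mask$values), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(r$mean_hqi, mean(r$quality$values))
})

test_that("habitat-quality change classifies per-cell differences", {
  a <- gridm(0.5, 4, 4)
  ch0 <- hq_change(a, a)
  expect_equal(unname(ch0$fractions[["stable"]]), 1)

  b <- a; b$values <- b$values + 0.1
  ch1 <- hq_change(a, b, tol = 0.01)
  expect_equal(unname(ch1$fractions[["improved"]]), 1)

  cb <- a
  cb$values <- a$values + 0.2 * (-1)^(row(a$values) + col(a$values))
  ch2 <- hq_change(a, cb, tol = 0.01)
  expect_equal(unname(ch2$fractions[["improved"]]), 0.5)
  expect_equal(unname(ch2$fractions[["degraded"]]), 0.5)

  expect_error(hq_change(a, gridm(0.5, 3, 3)), "not aligned")
})

test_that("threat and sensitivity configuration files round-trip", {
  dir <- withr::local_tempdir()
  src <- gridm(c(1, rep(0, 8)), 3, 3)
  write_grid(src, file.path(dir, "crop.asc"))
  yaml::write_yaml(list(cropland = list(weight = 0.6, max_dist_km = 1,
                                        decay = "linear",
                                        source = "crop.asc")),
                   file.path(dir, "threats.yaml"))
  th <- read_threats(file.path(dir, "threats.yaml"))
  expect_length(th, 1L)
  expect_equal(th[[1]]$weight, 0.6)
  expect_equal(th[[1]]$source$values, src$values)

  df <- data.frame(HABITAT = c(0.3, 1), S_cropland = c(0, 0.5),
                   S_road = c(0.3, 0.7),
                   row.names = c("cropland", "woodland"))
  write.csv(df, file.path(dir, "sensitivity.csv"))
  st <- read_sensitivity_csv(file.path(dir, "sensitivity.csv"))
  expect_equal(unname(st$habitat["woodland"]), 1)
  expect_equal(unname(st$sensitivity["woodland", "road"]), 0.7)
})
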