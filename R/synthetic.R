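#' Synthetic landscape scenarios
#'
#' The generator emulates the statistical structure of the provincial
#' inputs the pipeline was designed for: spatially autocorrelated
#' environmental surfaces, Gaussian-niche species occurrences, Markov
#' land-use transitions between time periods, a GDP surface coupled to
#' built-up land, and blob-shaped existing reserves. Every generator is
#' fully deterministic under the scenario seed; each stage derives its own
#' sub-seed by hashing the stage name so stages can be re-run
#' independently.
#'
#' @param seed integer master seed.
#' @param shape `c(rows, cols)` of the landscape grid (>= 20 x 20).
#' @param n_species number of species to simulate.
#' @param n_env number of environmental surfaces (>= 3; the first is an
#'   elevation-like layer).
#' @param periods labels of the time periods, earliest first.
#' @param markov_matrix 6 x 6 row-stochastic land-use transition matrix
#'   (rows/cols in legend code order).
#' @param niche_optima optional `n_species x n_env` matrix of niche optima
#'   on the standardized environmental scale; when NULL, magnitudes are
#'   drawn uniformly from [0.8, 1.4] with random sign under the scenario
#'   seed, placing each species away from the landscape-modal environment
#'   (the narrow-range specialist profile of rare protected plants).
#' @param niche_breadth Gaussian niche breadth (sd) per layer, in
#'   standardized environmental units.
#' @param n_occurrences occurrence records drawn per species.
#' @param jitter_occurrences jitter points uniformly within their cell so
#'   spatial thinning has sub-cell structure to work on.
#' @param gdp_coupling target minimum correlation between GDP and smoothed
#'   construction density.
#' @param reserve_fraction fraction of cells inside pre-existing reserves.
#' @param cell_size cell edge in metres.
#' @return A `landscape_scenario` list.
#' @examples
#' sc <- landscape_scenario(seed = 1, shape = c(40, 40))
#' env <- make_environment(sc)
#' names(env)
#' @export
landscape_scenario <- function(seed = 1L,
                               shape = c(120L, 120L),
                               n_species = 3L,
                               n_env = 3L,
                               periods = c("t0", "t1", "t2"),
                               markov_matrix = default_markov_matrix(),
                               niche_optima = NULL,
                               niche_breadth = 0.35,
                               n_occurrences = 40L,
                               jitter_occurrences = TRUE,
                               gdp_coupling = 0.6,
                               reserve_fraction = 0.10,
                               cell_size = 1000) {
  stopifnot(length(shape) == 2L, n_species >= 1L, n_env >= 3L,
            length(periods) >= 1L, reserve_fraction >= 0,
            reserve_fraction < 1, all(niche_breadth > 0))
  check_markov(markov_matrix)
  if (is.null(niche_optima)) {
    niche_optima <- with_stage_seed(seed, "niche", {
      mag <- stats::runif(n_species * n_env, 0.8, 1.4)
      sgn <- sample(c(-1, 1), n_species * n_env, replace = TRUE)
      matrix(mag * sgn, n_species, n_env)
    })
  }
  stopifnot(nrow(niche_optima) == n_species, ncol(niche_optima) == n_env)
  breadth <- rep_len(niche_breadth, n_env)
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 n_species = as.integer(n_species), n_env = as.integer(n_env),
                 periods = periods, markov_matrix = markov_matrix,
                 niche_optima = niche_optima, niche_breadth = breadth,
                 n_occurrences = as.integer(n_occurrences),
                 jitter_occurrences = isTRUE(jitter_occurrences),
                 gdp_coupling = gdp_coupling,
                 reserve_fraction = reserve_fraction,
                 cell_size = cell_size),
            class = "landscape_scenario")
}

#' Default land-use transition matrix
#'
#' A mildly dynamic row-stochastic matrix: classes are mostly persistent,
#' with cropland leaking to construction and woodland, grassland to
#' woodland/cropland, and a trickle of abandonment to unused land.
#' @return 6 x 6 matrix, rows and columns in legend code order.
#' @export
default_markov_matrix <- function() {
  m <- matrix(c(
    # to: crop  wood  grass water constr unused
    0.88, 0.04, 0.02, 0.01, 0.04, 0.01,  # cropland
    0.02, 0.94, 0.02, 0.01, 0.005, 0.005, # woodland
    0.05, 0.06, 0.85, 0.01, 0.02, 0.01,  # grassland
    0.02, 0.01, 0.01, 0.95, 0.005, 0.005, # water
    0.01, 0.005, 0.005, 0.00, 0.98, 0.00, # construction
    0.06, 0.04, 0.04, 0.01, 0.02, 0.83), # unused
    nrow = 6, byrow = TRUE)
  dimnames(m) <- list(names(landuse_legend()), names(landuse_legend()))
  m
}

check_markov <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(6L, 6L)) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-9))
    stop("markov_matrix must be 6x6, non-negative, rows summing to 1")
  invisible(TRUE)
}

# Stable stage sub-seed: polynomial hash of the stage name folded into the
# master seed, kept below 2^31 so set.seed() accepts it.
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# Box blur with edge replication; `r` = half-width, `passes` repeats.
box_blur <- function(m, r = 3L, passes = 2L) {
  for (p in seq_len(passes)) {
    m <- blur_1d(m, r)
    m <- t(blur_1d(t(m), r))
  }
  m
}

blur_1d <- function(m, r) {
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  cs <- apply(pad, 2L, cumsum)
  cs <- rbind(0, cs)
  (cs[(2L * r + 2L):(n + 2L * r + 1L), , drop = FALSE] -
     cs[1L:n, , drop = FALSE]) / (2L * r + 1L)
}

#' Generate spatially autocorrelated environmental surfaces
#'
#' Low-pass-filtered Gaussian noise plus a broad gradient trend,
#' standardized per surface to mean 0 and sd 1. The first surface is the
#' elevation-like layer used to drive land-use seeding.
#'
#' @param scenario a [landscape_scenario()].
#' @return Named list of [grid()]s (`elevation`, `moisture`,
#'   `temperature`, then `env4`...).
#' @export
make_environment <- function(scenario) {
  nr <- scenario$shape[1L]; nc <- scenario$shape[2L]
  if (nr < 20L || nc < 20L)
    stop("make_environment: shape must be at least 20 x 20")
  nms <- c("elevation", "moisture", "temperature",
           if (scenario$n_env > 3L) paste0("env", 4:scenario$n_env))
  with_stage_seed(scenario$seed, "environment", {
    rowg <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    colg <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    out <- lapply(seq_len(scenario$n_env), function(i) {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      sm <- box_blur(noise, r = 3L, passes = 3L)
      trend <- stats::runif(1, -0.5, 0.5) * rowg + stats::runif(1, -0.5, 0.5) * colg
      z <- sm / stats::sd(sm) + trend
      z <- (z - mean(z)) / stats::sd(z)
      grid(z, cell_size = scenario$cell_size)
    })
    names(out) <- nms
    out
  })
}

#' Generate a multi-period land-use series
#'
#' The first period is carved from the environment (high elevation to
#' woodland, wet lowlands to water, urban kernels to construction, the
#' rest split between cropland/grassland/unused); each later period is
#' drawn cell-wise from the scenario's Markov transition matrix
#' conditioned on the previous class.
#'
#' @param scenario a [landscape_scenario()].
#' @param environment output of [make_environment()].
#' @return Named list of [landuse_map()]s, one per period.
#' @export
make_landuse_series <- function(scenario, environment) {
  check_markov(scenario$markov_matrix)
  elev <- environment[[1L]]$values
  moist <- environment[[2L]]$values
  nr <- nrow(elev); nc <- ncol(elev)
  leg <- landuse_legend()
  with_stage_seed(scenario$seed, "landuse", {
    lu <- matrix(leg[["cropland"]], nr, nc)
    lu[elev > stats::quantile(elev, 0.55) & moist < stats::quantile(moist, 0.5)] <-
      leg[["grassland"]]
    lu[elev > stats::quantile(elev, 0.65)] <- leg[["woodland"]]
    lu[elev > stats::quantile(elev, 0.985)] <- leg[["unused"]]
    wet <- moist > stats::quantile(moist, 0.96) & elev < stats::quantile(elev, 0.5)
    lu[wet] <- leg[["water"]]
    # urban kernels in low, dry terrain
    low <- which(elev < stats::quantile(elev, 0.4) & !wet)
    n_centers <- max(2L, round(nr * nc / 3000))
    centers <- sample(low, min(n_centers, length(low)))
    crow <- (centers - 1L) %% nr + 1L; ccol <- (centers - 1L) %/% nr + 1L
    for (i in seq_along(centers)) {
      rr <- pmax(1L, crow[i] - 3L):pmin(nr, crow[i] + 3L)
      cc <- pmax(1L, ccol[i] - 3L):pmin(nc, ccol[i] + 3L)
      blk <- as.matrix(expand.grid(rr, cc))
      d <- sqrt((blk[, 1] - crow[i])^2 + (blk[, 2] - ccol[i])^2)
      keep <- blk[d <= 3, , drop = FALSE]
      lu[keep] <- leg[["construction"]]
    }
    maps <- list(landuse_map(grid(lu, cell_size = scenario$cell_size)))
    m <- scenario$markov_matrix
    cum <- t(apply(m, 1L, cumsum))
    for (p in seq_along(scenario$periods)[-1L]) {
      prev <- maps[[p - 1L]]$grid$values
      u <- matrix(stats::runif(nr * nc), nr, nc)
      nxt <- prev
      for (cls in 1:6) {
        idx <- which(prev == cls)
        if (!length(idx)) next
        nxt[idx] <- 1L + findInterval(u[idx], cum[cls, ],
                                      rightmost.closed = FALSE)
      }
      nxt[nxt > 6L] <- 6L
      maps[[p]] <- landuse_map(grid(nxt, cell_size = scenario$cell_size))
    }
    names(maps) <- scenario$periods
    maps
  })
}

#' True niche presence-probability surface
#'
#' Product of Gaussian responses over the environmental layers for one
#' species; the ground truth against which fitted suitability surfaces can
#' be benchmarked.
#'
#' @param scenario a [landscape_scenario()].
#' @param environment output of [make_environment()].
#' @param species species index (1..n_species).
#' @return A [grid()] of unnormalised presence probabilities in (0, 1].
#' @export
niche_probability <- function(scenario, environment, species) {
  stopifnot(species >= 1, species <= scenario$n_species)
  opt <- scenario$niche_optima[species, ]
  br <- scenario$niche_breadth
  p <- Reduce(`*`, lapply(seq_len(scenario$n_env), function(l) {
    exp(-(environment[[l]]$values - opt[l])^2 / (2 * br[l]^2))
  }))
  grid(p, cell_size = scenario$cell_size)
}

#' Sample species occurrence points
#'
#' Cells are drawn without replacement with probability proportional to
#' the species' Gaussian-niche response; by default points are jittered
#' uniformly within their cell so records have sub-cell coordinates.
#'
#' @param scenario a [landscape_scenario()].
#' @param environment output of [make_environment()].
#' @param n points per species (default `scenario$n_occurrences`).
#' @return data.frame with columns `species`, `x`, `y`.
#' @export
make_occurrences <- function(scenario, environment, n = scenario$n_occurrences) {
  g <- environment[[1L]]
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  with_stage_seed(scenario$seed, "occurrences", {
    out <- lapply(seq_len(scenario$n_species), function(s) {
      w <- as.vector(niche_probability(scenario, environment, s)$values)
      if (sum(w > 0) < n)
        stop("make_occurrences: only ", sum(w > 0),
             " cells with positive probability for species ", s,
             " but ", n, " requested")
      cells <- sample.int(length(w), n, prob = w)
      row <- (cells - 1L) %% nr + 1L
      col <- (cells - 1L) %/% nr + 1L
      jx <- if (scenario$jitter_occurrences) stats::runif(n, -0.5, 0.5) else 0
      jy <- if (scenario$jitter_occurrences) stats::runif(n, -0.5, 0.5) else 0
      data.frame(species = sprintf("species_%02d", s),
                 x = g$origin[1] + (col - 0.5 + jx) * cs,
                 y = g$origin[2] - (row - 0.5 + jy) * cs)
    })
    do.call(rbind, out)
  })
}

#' Generate ancillary surfaces: GDP, reserves, threat rasters
#'
#' GDP is smoothed construction density times positive multiplicative
#' noise; reserves are blob-shaped regions around random centres covering
#' the scenario's reserve fraction; threats are the cropland mask, the
#' construction mask, and a one-cell-wide synthetic road polyline.
#'
#' @param scenario a [landscape_scenario()].
#' @param landuse a [landuse_map()] (typically the first period).
#' @return list with `gdp` (grid), `reserves` (0/1 grid), `threats`
#'   (named list of grids: cropland, construction, road).
#' @export
make_ancillary <- function(scenario, landuse) {
  g <- landuse$grid
  nr <- nrow(g$values); nc <- ncol(g$values)
  with_stage_seed(scenario$seed, "ancillary", {
    constr <- landuse_mask(landuse, "construction")
    dens <- box_blur(ifelse(is.na(constr$values), 0, constr$values),
                     r = 3L, passes = 2L)
    noise <- exp(stats::rnorm(nr * nc, 0, 0.25))
    gdp_v <- (dens + 0.02) * matrix(noise, nr, nc)
    gdp <- grid(gdp_v, cell_size = g$cell_size, origin = g$origin)

    res <- matrix(0L, nr, nc)
    target <- round(scenario$reserve_fraction * nr * nc)
    if (target > 0) {
      n_centers <- max(1L, round(target / 150))
      ctr <- cbind(sample.int(nr, n_centers, replace = TRUE),
                   sample.int(nc, n_centers, replace = TRUE))
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      d2 <- matrix(Inf, nr, nc)
      for (i in seq_len(n_centers)) {
        # anisotropic stretch gives irregular blob shapes
        sx <- stats::runif(1, 0.6, 1.6)
        d2 <- pmin(d2, ((rows - ctr[i, 1]) * sx)^2 + ((cols - ctr[i, 2]) / sx)^2)
      }
      take <- order(as.vector(d2))[seq_len(target)]
      res[take] <- 1L
    }
    reserves <- grid(res, cell_size = g$cell_size, origin = g$origin)

    road <- matrix(0L, nr, nc)
    r <- sample.int(nr - 2L, 1L) + 1L
    for (cc in seq_len(nc)) {
      road[r, cc] <- 1L
      r <- min(max(r + sample(c(-1L, 0L, 1L), 1L), 1L), nr)
    }
    threats <- list(cropland = landuse_mask(landuse, "cropland"),
                    construction = constr,
                    road = grid(road, cell_size = g$cell_size, origin = g$origin))
    list(gdp = gdp, reserves = reserves, threats = threats)
  })
}

#' Write a full scenario to a directory
#'
#' Emits every generated layer as an ESRI ASCII grid, the occurrence table
#' as CSV, and a `scenario.yaml` echoing all parameters.
#'
#' @param scenario a [landscape_scenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- make_environment(scenario)
  lus <- make_landuse_series(scenario, env)
  occ <- make_occurrences(scenario, env)
  anc <- make_ancillary(scenario, lus[[1L]])
  for (nm in names(env))
    write_grid(env[[nm]], file.path(dir, paste0("env_", nm, ".asc")))
  for (p in names(lus))
    write_grid(lus[[p]]$grid, file.path(dir, paste0("landuse_", p, ".asc")))
  write_grid(anc$gdp, file.path(dir, "gdp.asc"))
  write_grid(anc$reserves, file.path(dir, "reserves.asc"))
  for (nm in names(anc$threats))
    write_grid(anc$threats[[nm]], file.path(dir, paste0("threat_", nm, ".asc")))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = scenario$seed, shape = scenario$shape,
                        n_species = scenario$n_species,
                        n_env = scenario$n_env, periods = scenario$periods,
                        niche_breadth = scenario$niche_breadth,
                        n_occurrences = scenario$n_occurrences,
                        gdp_coupling = scenario$gdp_coupling,
                        reserve_fraction = scenario$reserve_fraction,
                        markov_matrix = as.vector(scenario$markov_matrix)),
                   file.path(dir, "scenario.yaml"))
  invisible(list(environment = env, landuse = lus, occurrences = occ,
                 ancillary = anc))
}
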