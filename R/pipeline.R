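#' Pipeline configuration
#'
#' Bundles every stage's parameters with one master seed. The defaults
#' define the packaged demo scenario: a 120 x 120 km landscape, three
#' species, three periods, and desk-scale model settings chosen so the
#' full analysis completes in minutes while preserving every mechanism
#' of the full-scale study design.
#'
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it by stable name hashing, so adding a stage never
#'   perturbs earlier stages.
#' @param out_dir output directory for all artifacts.
#' @param scenario list of [landscape_scenario()] overrides.
#' @param sdm list: `runs`, `n_background`, `r_max`, `inclusion`, `l2`,
#'   `use_ehp`.
#' @param clfi_window window edge (cells) for fragmentation.
#' @param block_size planning-unit edge (cells).
#' @param target_fraction,spf conservation target fraction and penalty
#'   factor.
#' @param sa list: `blm`, `n_runs`, `iterations`, `cooling`.
#' @param gap_threshold selection-frequency cutoff for gaps.
#' @param hq_tol stable-band tolerance for habitat-quality change.
#' @param carbon_top,overlay_richness_min top carbon zones / minimum
#'   richness defining the overlay masks.
#' @param quiet suppress progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gapscape_"),
                            scenario = list(),
                            sdm = list(),
                            clfi_window = 20L,
                            block_size = 10L,
                            target_fraction = 0.3, spf = 5,
                            sa = list(),
                            gap_threshold = 0.65,
                            hq_tol = 0.01,
                            carbon_top = 2L,
                            overlay_richness_min = 1L,
                            quiet = FALSE) {
  scenario_def <- list(shape = c(120L, 120L), n_species = 3L, n_env = 3L,
                       periods = c("t0", "t1", "t2"))
  sdm_def <- list(runs = 10L, n_background = 500L, r_max = 0.8,
                  inclusion = 0.8, l2 = 0.01, use_ehp = TRUE)
  sa_def <- list(blm = 0.001, n_runs = 100L, iterations = 5000L,
                 cooling = 0.999)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 scenario = utils::modifyList(scenario_def, scenario),
                 sdm = utils::modifyList(sdm_def, sdm),
                 clfi_window = clfi_window, block_size = block_size,
                 target_fraction = target_fraction, spf = spf,
                 sa = utils::modifyList(sa_def, sa),
                 gap_threshold = gap_threshold, hq_tol = hq_tol,
                 carbon_top = carbon_top,
                 overlay_richness_min = overlay_richness_min,
                 quiet = quiet), class = "pipeline_config")
}

pipe_log <- function(config, stage, msg) {
  if (!isTRUE(config$quiet))
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                    stage, msg))
}

#' Run the full conservation-gap analysis
#'
#' Executes, for each period: habitat quality, carbon accounting, the SDM
#' ensemble per species with richness stacking, windowed fragmentation of
#' the species and habitat masks, the entropy-weighted disturbance cost,
#' planning-unit prioritisation by repeated simulated annealing, the
#' eight-category overlay, and gap extraction; then intersects gaps
#' across periods. All artifacts are written under `config$out_dir` and
#' listed, with MD5 hashes, in `manifest.json`; reruns with the same
#' config and seed reproduce the hashes exactly. On a stage failure the
#' run aborts naming the stage, and that stage's partial files are kept
#' with a `.partial` suffix.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly written to `manifest.json`): file
#'   list + hashes plus headline summary numbers.
#' @export
run_all <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage_files <- character(0)
  current_stage <- "setup"
  emit <- function(path) {
    stage_files <<- c(stage_files, path)
    written <<- c(written, path)
    path
  }
  begin <- function(stage) {
    current_stage <<- stage
    stage_files <<- character(0)
  }
  run_stage <- function(stage, expr) {
    begin(stage)
    tryCatch(expr, error = function(e) {
      for (f in stage_files) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)

  # --- generate -----------------------------------------------------------
  sc <- do.call(landscape_scenario,
                c(list(seed = stage_seed(config$seed, "scenario")),
                  config$scenario))
  gen <- run_stage("generate", {
    pipe_log(config, "generate", "synthesising scenario inputs")
    env <- make_environment(sc)
    lus <- make_landuse_series(sc, env)
    occ <- make_occurrences(sc, env)
    anc <- lapply(lus, function(lu) make_ancillary(sc, lu))
    for (nm in names(env))
      emit(write_grid(env[[nm]], file.path(out, paste0("env_", nm, ".asc"))))
    for (p in names(lus))
      emit(write_grid(lus[[p]]$grid,
                      file.path(out, paste0("landuse_", p, ".asc"))))
    emit(write_grid(anc[[1L]]$reserves, file.path(out, "reserves.asc")))
    utils::write.csv(occ, emit(file.path(out, "occurrences.csv")),
                     row.names = FALSE)
    list(env = env, lus = lus, occ = occ, anc = anc)
  })
  periods <- names(gen$lus)

  # --- habitat quality ----------------------------------------------------
  hq <- run_stage("hq", {
    res <- list()
    for (p in periods) {
      pipe_log(config, "hq", paste("period", p))
      thr <- default_threats(gen$anc[[p]]$threats)
      D <- degradation(thr, default_sensitivity(), gen$lus[[p]])
      res[[p]] <- hq_quality(D, gen$lus[[p]], default_sensitivity())
      emit(write_grid(res[[p]]$quality,
                      file.path(out, paste0("quality_", p, ".asc"))))
      emit(write_grid(res[[p]]$classes,
                      file.path(out, paste0("quality_class_", p, ".asc"))))
    }
    res
  })
  summary$mean_hqi <- vapply(hq, `[[`, numeric(1), "mean_hqi")
  chg <- hq_change(hq[[1L]]$quality, hq[[length(hq)]]$quality,
                   tol = config$hq_tol)
  summary$hq_change_fractions <- as.list(chg$fractions)

  # --- carbon -------------------------------------------------------------
  carbon <- run_stage("carbon", {
    res <- list()
    for (p in periods) {
      res[[p]] <- carbon_map(gen$lus[[p]])
      emit(write_grid(res[[p]]$density_grid,
                      file.path(out, paste0("carbon_density_", p, ".asc"))))
      emit(write_grid(res[[p]]$zones,
                      file.path(out, paste0("carbon_zones_", p, ".asc"))))
    }
    pipe_log(config, "carbon",
             sprintf("total C t0 = %.4g t", res[[1L]]$total_C))
    res
  })
  summary$total_carbon_t <- vapply(carbon, `[[`, numeric(1), "total_C")
  summary$carbon_delta_t <- carbon[[length(carbon)]]$total_C -
    carbon[[1L]]$total_C

  # --- sdm ----------------------------------------------------------------
  sdm <- run_stage("sdm", {
    res <- list()
    species <- unique(gen$occ$species)
    for (p in periods) {
      layers <- gen$env
      if (isTRUE(config$sdm$use_ehp))
        layers <- c(layers, ehp_covariates(gen$lus[[p]],
                                           config$clfi_window))
      per_sp <- list()
      for (s in species) {
        pipe_log(config, "sdm", paste(p, s))
        pts <- gen$occ[gen$occ$species == s, ]
        pts <- thin_occurrences(pts, radius_km = 1,
                                seed = stage_seed(config$seed,
                                                  paste0("thin_", s)))
        lay_s <- filter_predictors(layers, pts, r_max = config$sdm$r_max)
        per_sp[[s]] <- sdm_ensemble(
          pts, lay_s, runs = config$sdm$runs,
          inclusion_threshold = config$sdm$inclusion,
          n_background = config$sdm$n_background, l2 = config$sdm$l2,
          seed = stage_seed(config$seed, paste0("sdm_", p, "_", s)))
        emit(write_grid(per_sp[[s]]$p_ens,
                        file.path(out, paste0("suitability_", p, "_", s,
                                              ".asc"))))
      }
      rich <- stack_richness(per_sp)
      emit(write_grid(rich$richness,
                      file.path(out, paste0("richness_", p, ".asc"))))
      res[[p]] <- list(ensembles = per_sp, richness = rich)
    }
    res
  })
  eval_tab <- do.call(rbind, lapply(periods, function(p) {
    do.call(rbind, lapply(names(sdm[[p]]$ensembles), function(s) {
      e <- sdm[[p]]$ensembles[[s]]
      data.frame(period = p, species = s, auc = e$holdout$auc,
                 tss = e$holdout$tss, threshold = e$threshold)
    }))
  }))
  utils::write.csv(eval_tab, file.path(out, "evaluation.csv"),
                   row.names = FALSE)
  written <- c(written, file.path(out, "evaluation.csv"))
  summary$mean_holdout_auc <- mean(eval_tab$auc)
  summary$mean_holdout_tss <- mean(eval_tab$tss)

  # --- masks per period ---------------------------------------------------
  masks <- lapply(periods, function(p) {
    rich <- sdm[[p]]$richness$richness
    sp_high <- grid(ifelse(is.na(rich$values), NA_integer_,
                           as.integer(rich$values >=
                                        config$overlay_richness_min)),
                    cell_size = rich$cell_size, origin = rich$origin)
    list(species = sp_high,
         habitat = hq[[p]]$high_value_mask,
         carbon = carbon_high_mask(carbon[[p]], config$carbon_top))
  })
  names(masks) <- periods

  # --- fragmentation ------------------------------------------------------
  frag <- run_stage("clfi", {
    sp_masks <- lapply(masks, `[[`, "species")
    hb_masks <- lapply(masks, `[[`, "habitat")
    f1 <- clfi(sp_masks, config$clfi_window)
    f2 <- clfi(hb_masks, config$clfi_window)
    for (p in periods) {
      emit(write_grid(f1[[p]]$clfi_grid,
                      file.path(out, paste0("clfi_species_", p, ".asc"))))
      emit(write_grid(f2[[p]]$clfi_grid,
                      file.path(out, paste0("clfi_habitat_", p, ".asc"))))
    }
    list(species = f1, habitat = f2)
  })
  summary$clfi_species <- vapply(frag$species, `[[`, numeric(1), "mean_clfi")
  summary$clfi_habitat <- vapply(frag$habitat, `[[`, numeric(1), "mean_clfi")

  # --- cost (HDI) ---------------------------------------------------------
  cost <- run_stage("hdi", {
    res <- list()
    for (p in periods) {
      ind <- list(gdp = gen$anc[[p]]$gdp,
                  landuse = landuse_disturbance(gen$lus[[p]]))
      w <- entropy_weights(ind)
      res[[p]] <- list(hdi = hdi(ind, w), weights = w)
      emit(write_grid(res[[p]]$hdi,
                      file.path(out, paste0("hdi_", p, ".asc"))))
    }
    jsonlite::write_json(
      lapply(res, function(r) as.list(r$weights$weights)),
      emit(file.path(out, "hdi_weights.json")), auto_unbox = TRUE,
      digits = NA)
    res
  })
  summary$entropy_weights <- lapply(cost, function(r)
    as.list(r$weights$weights))

  # --- prioritisation -----------------------------------------------------
  prio <- run_stage("prioritize", {
    res <- list()
    for (p in periods) {
      pipe_log(config, "prioritize", paste("period", p))
      feats <- c(lapply(sdm[[p]]$ensembles, `[[`, "high_mask"),
                 list(habitat = masks[[p]]$habitat,
                      carbon = masks[[p]]$carbon))
      pu <- build_units(feats, cost[[p]]$hdi,
                        reserves = gen$anc[[1L]]$reserves,
                        block_size = config$block_size)
      ft <- feature_targets(pu, target_fraction = config$target_fraction,
                            spf = config$spf)
      params <- sa_params(blm = config$sa$blm, n_runs = config$sa$n_runs,
                          iterations = config$sa$iterations,
                          cooling = config$sa$cooling,
                          seed = stage_seed(config$seed,
                                            paste0("sa_", p)))
      sf <- ssoln(pu, ft, params)
      gaps <- extract_gaps(sf, pu, config$gap_threshold)
      utils::write.csv(data.frame(id = pu$units$id, ssoln = sf$ssoln),
                       emit(file.path(out, paste0("ssoln_", p, ".csv"))),
                       row.names = FALSE)
      emit(write_units_geojson(pu, gaps,
                               file.path(out, paste0("gaps_", p,
                                                     ".geojson"))))
      res[[p]] <- list(pu = pu, ft = ft, sf = sf, gaps = gaps)
    }
    res
  })
  summary$gap_counts <- vapply(prio, function(r) length(r$gaps), integer(1))

  # --- overlay + persistent gaps -----------------------------------------
  gaps_final <- run_stage("overlay", {
    shares <- list()
    for (p in periods) {
      ov <- overlay_priorities(masks[[p]]$species, masks[[p]]$habitat,
                               masks[[p]]$carbon)
      emit(write_grid(ov$categories,
                      file.path(out, paste0("overlay_", p, ".asc"))))
      shares[[p]] <- as.list(ov$shares)
    }
    pg <- persistent_gaps(lapply(prio, `[[`, "gaps"))
    emit(write_units_geojson(prio[[1L]]$pu, pg$persistent,
                             file.path(out, "persistent_gaps.geojson")))
    list(shares = shares, persistent = pg)
  })
  summary$overlay_shares <- gaps_final$shares
  summary$persistent_gap_count <- gaps_final$persistent$persistent_count
  summary$persistent_gaps <- gaps_final$persistent$persistent

  # --- manifest -----------------------------------------------------------
  written <- sort(unique(written[file.exists(written)]))
  manifest <- list(
    config = list(seed = config$seed, periods = periods,
                  shape = sc$shape, n_species = sc$n_species),
    files = lapply(written, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    summary = summary)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(config, "done", paste("manifest written to", out))
  invisible(manifest)
}
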