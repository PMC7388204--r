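# End-to-end orchestration: simulate -> crosswalk -> vif -> stack -> fit ->
# predict -> aggregate -> inequality -> counterfactual -> validate, with a
# provenance manifest (stage order, seeds, artifact hashes).

#' Pipeline configuration
#'
#' @param grid A [grid_spec()] (default desk-scale world).
#' @param indicators Indicators to model, subset of `c("ORS","RHF","ORT")`.
#' @param survey_design Passed to [simulate_surveys()] via [simulate_world()].
#' @param n_draws Posterior draws per surface (default 250).
#' @param vif_threshold VIF threshold for covariate filtering (default 3).
#' @param mbg Options forwarded to [mbg_spec()] for the regional fits;
#'   defaults to `list(optim_maxit = 60, n_hyper = 8)`, a desk-scale
#'   setting that matches the full default within Monte Carlo error.
#' @param cv List `k` (folds, default 5), `n_draws` (default 100); the
#'   validate stage runs on the first indicator's first-region records.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = grid_spec(),
                            indicators = c("ORS", "RHF", "ORT"),
                            survey_design = list(), n_draws = 250L,
                            vif_threshold = 3,
                            mbg = list(optim_maxit = 60L, n_hyper = 8L),
                            cv = list(k = 5L, n_draws = 100L),
                            seed = 1L, out_dir = NULL) {
  indicators <- match.arg(indicators, c("ORS", "RHF", "ORT"),
                          several.ok = TRUE)
  structure(list(grid = grid, indicators = indicators,
                 survey_design = survey_design, n_draws = as.integer(n_draws),
                 vif_threshold = vif_threshold, mbg = mbg, cv = cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic content hash of an R object (serialized, md5)
hash_obj <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] (indicators, n_draws, vif_threshold,
#' seed, survey_design entries, grid dimensions) may be given in a YAML
#' file; unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  g <- do.call(grid_spec, y$grid %||% list())
  pipeline_config(
    grid = g,
    indicators = y$indicators %||% c("ORS", "RHF", "ORT"),
    survey_design = y$survey_design %||% list(),
    n_draws = y$n_draws %||% 250L,
    vif_threshold = y$vif_threshold %||% 3,
    mbg = y$mbg %||% list(),
    cv = y$cv %||% list(k = 5L, n_draws = 100L),
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

#' Run the full coverage-mapping pipeline
#'
#' Executes every stage on a seeded synthetic world: world simulation,
#' definition crosswalk (auto-skipped for indicators without non-standard
#' records), per-region VIF covariate filtering, per-(indicator, region)
#' stacked generalisation and geostatistical fits, joint posterior surface
#' draws stitched across regions, population-weighted admin aggregation
#' with AROC and untreated counts, inequality metrics, counterfactual
#' deaths analysis, and admin2-blocked cross-validation. Returns all
#' artifacts plus a manifest of stage order, seeds and content hashes;
#' rerunning with the same config reproduces the hashes bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log lines (timestamped, to stderr)?
#' @return List of class `pipeline_result`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  manifest <- list()
  log_stage <- function(name, note = "") {
    if (!quiet)
      message(sprintf("[%s] stage %-12s %s",
                      format(Sys.time(), "%H:%M:%S"), name, note))
  }
  add_stage <- function(name, status, seed, obj) {
    manifest[[length(manifest) + 1L]] <<-
      list(stage = name, status = status, seed = seed,
           hash = if (!is.null(obj)) hash_obj(obj) else NA_character_)
  }
  stage_guard <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed
  grid <- config$grid
  regions <- sort(unique(grid$membership$region_id))

  # 1. simulate ---------------------------------------------------------
  log_stage("simulate")
  world <- stage_guard("simulate",
    simulate_world(grid, indicators = config$indicators,
                   survey_design = config$survey_design, seed = seed))
  add_stage("simulate", "done", seed, world$observations)

  # 2. crosswalk --------------------------------------------------------
  obs_adj <- list(); xwalk <- list()
  for (ind in config$indicators) {
    o <- world$observations[[ind]]
    non <- o$definition == "nonstandard"
    paired <- intersect(unique(o$survey_id[non]),
                        unique(o$survey_id[!non]))
    if (any(non) && length(paired) >= 2L) {
      log_stage("crosswalk", ind)
      m <- stage_guard("crosswalk", fit_definition_adjustment(o))
      obs_adj[[ind]] <- apply_adjustment(o, m)
      xwalk[[ind]] <- m
    } else {
      if (any(non))
        warning("indicator ", ind, ": not enough calibration overlap; ",
                "non-standard records used unadjusted", call. = FALSE)
      obs_adj[[ind]] <- o  # stage auto-skips: nothing to crosswalk
    }
  }
  add_stage("crosswalk",
            if (length(xwalk)) "done" else "skipped", seed, xwalk)

  # 3. vif per region ---------------------------------------------------
  log_stage("vif")
  vif_reports <- list()
  retained <- list()
  for (r in regions) {
    cells <- grid$membership$cell_id[grid$membership$region_id == r] + 1L
    Xr <- do.call(rbind, lapply(seq_along(grid$years), function(t)
      matrix(world$covariates$values[cells, t, ],
             nrow = length(cells),
             dimnames = list(NULL, world$covariates$layers))))
    rep_r <- stage_guard("vif",
      vif_filter(Xr, threshold = config$vif_threshold, region = r))
    vif_reports[[as.character(r)]] <- rep_r
    retained[[as.character(r)]] <- rep_r$retained
  }
  add_stage("vif", "done", seed, lapply(vif_reports, `[[`, "retained"))

  # 4-6. stack, fit, predict per (indicator, region) --------------------
  fits <- list(); bundles <- list(); cubes <- list()
  region_designs <- list()
  n_t <- length(grid$years)
  for (ind in config$indicators) {
    cube_p <- array(NA_real_, c(grid$n_cells, n_t, config$n_draws))
    for (r in regions) {
      key <- paste0(ind, ".", r)
      rcells <- grid$membership$cell_id[grid$membership$region_id == r]
      o <- obs_adj[[ind]]
      in_region <- (o$geo_type == "point" & o$cell_id %in% rcells) |
        (o$geo_type == "polygon" &
           o$polygon_id %in% grid$membership$admin1_id[
             grid$membership$region_id == r])
      o_r <- o[in_region, ]
      seed_sr <- seed + 1000L * match(ind, config$indicators) + 10L * r
      log_stage("stack", key)
      bundle <- stage_guard("stack",
        fit_child_learners(o_r, world$covariates, world$population,
                           layers = retained[[as.character(r)]],
                           seed = seed_sr))
      bundles[[key]] <- bundle
      des <- stack_design(bundle)
      w <- stack_weights(bundle, o_r)
      comb <- combine_stackers(des, w)
      design <- list(obs = matrix(comb$obs, ncol = 1L,
                                  dimnames = list(NULL, "stacker")),
                     grid = comb$grid)
      region_designs[[key]] <- list(design = design, obs = o_r,
                                    weights = w)
      log_stage("fit", key)
      fit <- stage_guard("fit",
        mbg(o_r, grid, design = design, pop = world$population,
            spec = do.call(mbg_spec, c(config$mbg, list(region = r))),
            seed = seed_sr))
      fits[[key]] <- fit
      log_stage("predict", key)
      dc <- stage_guard("predict",
        draw_posterior_surfaces(fit, n_draws = config$n_draws,
                                seed = seed_sr))
      cube_p[rcells + 1L, , ] <- dc$p[rcells + 1L, , ]
    }
    cubes[[ind]] <- structure(list(p = cube_p, grid = grid,
                                   n_draws = config$n_draws),
                              class = "draw_cube")
  }
  add_stage("stack", "done", seed, lapply(bundles, `[[`, "oof"))
  add_stage("fit", "done", seed, lapply(fits, `[[`, "theta_mode"))
  add_stage("predict", "done", seed, lapply(cubes, function(x) dim(x$p)))

  # 7. aggregate --------------------------------------------------------
  log_stage("aggregate")
  aggregates <- stage_guard("aggregate", {
    out <- list()
    for (ind in config$indicators)
      out[[ind]] <- list(
        admin2 = aggregate_draws(cubes[[ind]], world$population, "admin2"),
        admin1 = aggregate_draws(cubes[[ind]], world$population, "admin1"),
        country = aggregate_draws(cubes[[ind]], world$population, "country"))
    out
  })
  y0 <- grid$years[1L]; y1 <- grid$years[n_t]
  aroc <- lapply(aggregates, function(a) compute_aroc(a$admin2, y0, y1))
  untreated <- stage_guard("aggregate", {
    ind_u <- if ("ORT" %in% config$indicators) "ORT" else
      config$indicators[1L]
    count_untreated(cubes[[ind_u]], world$episodes, "admin2", y1)
  })
  trend_cor <- if (all(c("ORS", "RHF") %in% config$indicators)) {
    correlate_trends(aggregates$ORS$admin2, aggregates$RHF$admin2)
  } else NULL
  add_stage("aggregate", "done", seed,
            lapply(aggregates, function(a) a$admin2$summary))

  # 8. inequality -------------------------------------------------------
  log_stage("inequality")
  ind_i <- if ("ORS" %in% config$indicators) "ORS" else config$indicators[1L]
  ineq <- stage_guard("inequality", {
    r0 <- inequality_record(aggregates[[ind_i]]$admin2, grid$membership, y0)
    r1 <- inequality_record(aggregates[[ind_i]]$admin2, grid$membership, y1)
    list(baseline = r0, final = r1, trends = inequality_trends(r0, r1))
  })
  add_stage("inequality", "done", seed, ineq$trends$counts)

  # 9. counterfactual ---------------------------------------------------
  cf <- NULL
  if ("ORS" %in% config$indicators && !is.null(world$mortality)) {
    log_stage("counterfactual")
    cf <- stage_guard("counterfactual",
      run_counterfactual(world$mortality, aggregates$ORS$admin2,
                         world$population, y0, y1))
    add_stage("counterfactual", "done", seed,
              lapply(cf, function(s) s$totals))
  } else add_stage("counterfactual", "skipped", seed, NULL)

  # 10. validate --------------------------------------------------------
  log_stage("validate")
  key1 <- paste0(config$indicators[1L], ".", regions[1L])
  rd <- region_designs[[key1]]
  cv <- stage_guard("validate",
    cross_validate(rd$obs, grid, design = rd$design,
                   pop = world$population, k = config$cv$k %||% 5L,
                   spec = do.call(mbg_spec, config$mbg),
                   n_draws = config$cv$n_draws %||% 100L, seed = seed + 7L))
  add_stage("validate", "done", seed + 7L,
            cv$pooled[c("bias", "rmse", "coverage95")])

  result <- structure(
    list(world = world, obs_adj = obs_adj, crosswalk = xwalk,
         vif = vif_reports, bundles = bundles, fits = fits, cubes = cubes,
         aggregates = aggregates, aroc = aroc, untreated = untreated,
         trend_cor = trend_cor, inequality = ineq, counterfactual = cf,
         cv = cv, manifest = manifest, config = config,
         elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result,
                                                       config$out_dir)
  result
}

#' @method print pipeline_result
#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d stages, %.1f s elapsed\n",
              length(x$manifest), x$elapsed))
  for (st in x$manifest)
    cat(sprintf("  %-14s %-8s %s\n", st$stage, st$status,
                substr(st$hash %||% "", 1L, 8L)))
  invisible(x)
}

# write CSV/JSON artifacts for a pipeline run
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_membership(result$config$grid, file.path(out_dir, "membership.csv"))
  for (ind in names(result$obs_adj))
    write_observations(result$obs_adj[[ind]],
                       file.path(out_dir, sprintf("obs_%s.csv", ind)))
  for (ind in names(result$aggregates))
    utils::write.csv(result$aggregates[[ind]]$admin2$summary,
                     file.path(out_dir, sprintf("agg_admin2_%s.csv", ind)),
                     row.names = FALSE)
  for (ind in names(result$aroc))
    utils::write.csv(result$aroc[[ind]],
                     file.path(out_dir, sprintf("aroc_%s.csv", ind)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(manifest = result$manifest,
         inequality = result$inequality$trends$counts,
         cv = result$cv$pooled[c("bias", "rmse", "coverage95",
                                 "pearson_r")]),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
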