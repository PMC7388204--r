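#' Parameters of the generative coverage model
#'
#' Bundles the truth parameters used by [simulate_truth()]: the coverage
#' surface is `plogis(alpha + X beta + trend * (year - year0) + GP)` where
#' the Gaussian process has separable Matern 3/2 (space) x AR1 (time)
#' covariance and `tau2_nugget` is cluster-level logit noise applied when
#' surveys are drawn, not in the surface itself.
#'
#' @param alpha Intercept on the logit scale.
#' @param beta Covariate effects (logit scale), one per covariate layer.
#' @param sigma2_sp Marginal variance of the space-time field (>= 0).
#' @param range_sp Matern spatial range in cell units (> 0).
#' @param rho_t AR1 temporal correlation, |rho_t| < 1.
#' @param tau2_nugget Cluster-level nugget variance (>= 0).
#' @param trend Annual drift on the logit scale (positive for rising ORS,
#'   negative for falling RHF).
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(alpha = 0, beta = numeric(), sigma2_sp = 0.5,
                         range_sp = 8, rho_t = 0.8, tau2_nugget = 0.05,
                         trend = 0) {
  stopifnot(sigma2_sp >= 0, tau2_nugget >= 0, abs(rho_t) < 1, range_sp > 0)
  structure(list(alpha = alpha, beta = beta, sigma2_sp = sigma2_sp,
                 range_sp = range_sp, rho_t = rho_t,
                 tau2_nugget = tau2_nugget, trend = trend),
            class = "truth_params")
}

#' Simulate standardized spatial covariate layers
#'
#' Each layer is a smooth random field (a Matern 3/2 draw plus white noise),
#' constant over years, standardized to mean 0 / variance 1 across cells.
#' The last `collinear_pairs` layers are near-linear combinations of earlier
#' layers (plus a little noise) so that multicollinearity filtering has
#' something to find.
#'
#' @param grid A [grid_spec()].
#' @param n_layers Number of covariate layers (>= 2).
#' @param collinear_pairs How many layers to make near-collinear
#'   (< `n_layers`).
#' @param range_sp Spatial range of the smooth component.
#' @param noise_sd White-noise standard deviation added to the smooth field.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A [raster_cube()] with layers `cov_01`, `cov_02`, ...
#' @export
simulate_covariates <- function(grid, n_layers = 8L, collinear_pairs = 1L,
                                range_sp = 6, noise_sd = 0.2, seed = 1L) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 2L) stop("need at least 2 covariate layers", call. = FALSE)
  if (collinear_pairs >= n_layers)
    stop("collinear_pairs must be smaller than n_layers", call. = FALSE)
  set.seed(seed)
  n_free <- n_layers - collinear_pairs
  D <- as.matrix(stats::dist(grid$coords))
  R_s <- chol_jitter(matern32(D, range_sp))
  base <- matrix(0, grid$n_cells, n_layers)
  for (j in seq_len(n_free)) {
    f <- t(R_s) %*% stats::rnorm(grid$n_cells) +
      stats::rnorm(grid$n_cells, sd = noise_sd)
    base[, j] <- f
  }
  for (j in seq_len(collinear_pairs)) {
    w <- stats::rnorm(min(3L, n_free))
    parents <- sample.int(n_free, length(w))
    base[, n_free + j] <- base[, parents, drop = FALSE] %*% w +
      stats::rnorm(grid$n_cells, sd = 0.05)
  }
  base <- scale(base)
  vals <- array(NA_real_, c(grid$n_cells, length(grid$years), n_layers))
  for (j in seq_len(n_layers)) vals[, , j] <- base[, j]
  raster_cube(vals, grid, sprintf("cov_%02d", seq_len(n_layers)))
}

#' Simulate a true coverage surface
#'
#' Draws one realization of the generative model: logit coverage equals
#' intercept + covariate effects + annual trend + a separable space-time
#' Gaussian field. ORS-like indicators default to a positive trend and
#' RHF-like ones to a negative trend, emulating rising ORS / falling RHF use.
#'
#' @param grid A [grid_spec()].
#' @param covs Covariate [raster_cube()] (may be `NULL` when `beta` is empty).
#' @param params A [truth_params()]; `length(beta)` must equal the number of
#'   covariate layers.
#' @param indicator `"ORS"`, `"RHF"` or `"ORT"` (metadata; also sets the
#'   default trend sign when `params$trend` is 0 and `default_trend` is TRUE).
#' @param seed Integer seed.
#' @param default_trend Apply the indicator's conventional trend sign
#'   (+0.08/yr ORS, -0.08/yr RHF) when `params$trend == 0`? Default FALSE.
#' @return A single-layer [raster_cube()] of probabilities named `p`.
#' @export
simulate_truth <- function(grid, covs, params, indicator = "ORS", seed = 1L,
                           default_trend = FALSE) {
  stopifnot(inherits(params, "truth_params"))
  n_beta <- length(params$beta)
  if (n_beta > 0) {
    if (is.null(covs) || dim(covs$values)[3L] != n_beta)
      stop("length(beta) must match the number of covariate layers",
           call. = FALSE)
  }
  trend <- params$trend
  if (trend == 0 && default_trend)
    trend <- switch(indicator, ORS = 0.08, RHF = -0.08, 0)
  set.seed(seed)
  n_t <- length(grid$years)
  eta <- matrix(params$alpha, grid$n_cells, n_t)
  if (n_beta > 0) {
    for (t in seq_len(n_t))
      eta[, t] <- eta[, t] + covs$values[, t, ] %*% params$beta
  }
  yr0 <- grid$years[1L]
  eta <- eta + outer(rep(1, grid$n_cells), trend * (grid$years - yr0))
  eta <- eta + sim_st_field(grid, params$sigma2_sp, params$range_sp,
                            params$rho_t)
  p <- stats::plogis(eta)
  cube <- raster_cube(p, grid, "p")
  attr(cube, "indicator") <- indicator
  attr(cube, "tau2_nugget") <- params$tau2_nugget
  cube
}

#' Simulate a population surface
#'
#' Log-normal-ish smooth population density, constant over years, scaled to
#' a given total of children under 5.
#'
#' @param grid A [grid_spec()].
#' @param total Total population across cells per year.
#' @param range_sp Spatial range of the log-density field.
#' @param seed Integer seed.
#' @return A single-layer [raster_cube()] named `pop`.
#' @export
simulate_population <- function(grid, total = 1e6, range_sp = 10, seed = 1L) {
  set.seed(seed)
  f <- sim_st_field(grid, 0.7, range_sp, 0.99)[, 1L]
  w <- exp(f); w <- w / sum(w) * total
  raster_cube(matrix(w, grid$n_cells, length(grid$years)), grid, "pop")
}

#' Simulate cluster-survey observations of treatment coverage
#'
#' Emulates the structure of household-survey coverage data: cluster cells
#' are sampled proportionally to population; each cluster observes `N`
#' children under 5 with diarrhoea (N = 1 + Poisson(mean_N - 1), so N >= 1
#' and denominators stay small, as in real diarrhoea-treatment modules) and
#' `k ~ Binomial(N, p)` treated. A fraction of records are
#' polygon-referenced: they carry an admin1 id instead of a cell id and
#' their `p` is the population-weighted mean over the admin1's cells. For
#' RHF-like indicators, a fraction of surveys use a non-standard indicator
#' definition, shifting the cluster probability by `defn_offset` on the
#' logit scale; a subset of those surveys report each cluster under both
#' definitions, providing the calibration overlap the crosswalk needs.
#'
#' @param truth Truth [raster_cube()] from [simulate_truth()].
#' @param pop Population [raster_cube()].
#' @param design List of design knobs: `n_surveys` (default 12),
#'   `clusters_per_survey` (50), `mean_N` (8), `polygon_fraction` (0.1),
#'   `nonstandard_fraction` (0, typically > 0 for RHF), `both_fraction`
#'   (share of nonstandard surveys also reporting the standard definition,
#'   default 0.8 -- surveys fielding a non-standard module usually record
#'   the standard one too, which is what makes crosswalk calibration
#'   possible), `defn_offset` (logit shift of the nonstandard definition,
#'   default -0.5).
#' @param seed Integer seed.
#' @return An observation data frame of class `observation_set` with columns
#'   `survey_id`, `year`, `geo_type` ("point"/"polygon"), `cell_id`,
#'   `polygon_id` (admin1 id for polygon records), `N`, `k`, `indicator`,
#'   `definition` ("standard"/"nonstandard").
#' @export
simulate_surveys <- function(truth, pop, design = list(), seed = 1L) {
  d <- utils::modifyList(
    list(n_surveys = 12L, clusters_per_survey = 50L, mean_N = 8,
         polygon_fraction = 0.1, nonstandard_fraction = 0,
         both_fraction = 0.8, defn_offset = -0.5),
    design)
  stopifnot(d$mean_N >= 1, d$polygon_fraction >= 0, d$polygon_fraction <= 1,
            d$nonstandard_fraction >= 0, d$nonstandard_fraction <= 1)
  grid <- truth$grid
  indicator <- attr(truth, "indicator") %||% "ORS"
  tau2 <- attr(truth, "tau2_nugget") %||% 0
  p_mat <- cube_layer(truth, "p")
  pop_mat <- cube_layer(pop, 1L)
  if (sum(pop_mat[, 1L]) <= 0) stop("zero total population", call. = FALSE)
  set.seed(seed)

  years <- grid$years
  mem <- grid$membership
  out <- vector("list", d$n_surveys)
  for (s in seq_len(d$n_surveys)) {
    yr_idx <- ((s - 1L) %% length(years)) + 1L
    nonstd_survey <- stats::runif(1) < d$nonstandard_fraction
    both_survey <- nonstd_survey && stats::runif(1) < d$both_fraction
    nc <- d$clusters_per_survey
    cells <- sample.int(grid$n_cells, nc, replace = TRUE,
                        prob = pop_mat[, yr_idx]) - 1L
    is_poly <- stats::runif(nc) < d$polygon_fraction
    N <- 1L + stats::rpois(nc, d$mean_N - 1)
    eta <- stats::qlogis(pmin(pmax(p_mat[cells + 1L, yr_idx], 1e-12),
                              1 - 1e-12))
    # polygon records: population-weighted mean coverage over admin1 cells
    if (any(is_poly)) {
      a1 <- mem$admin1_id[cells + 1L]
      for (i in which(is_poly)) {
        m <- mem$cell_id[mem$admin1_id == a1[i]]
        w <- pop_mat[m + 1L, yr_idx]
        pbar <- sum(w * p_mat[m + 1L, yr_idx]) / sum(w)
        eta[i] <- stats::qlogis(pmin(pmax(pbar, 1e-12), 1 - 1e-12))
      }
    }
    if (tau2 > 0) eta <- eta + stats::rnorm(nc, sd = sqrt(tau2))

    mk_rec <- function(defn) {
      p_cl <- stats::plogis(eta + if (defn == "nonstandard") d$defn_offset else 0)
      data.frame(
        survey_id = sprintf("svy_%03d", s),
        year = years[yr_idx],
        geo_type = ifelse(is_poly, "polygon", "point"),
        cell_id = ifelse(is_poly, NA_integer_, cells),
        polygon_id = ifelse(is_poly, mem$admin1_id[cells + 1L], NA_integer_),
        N = N,
        k = stats::rbinom(nc, N, p_cl),
        indicator = indicator,
        definition = defn,
        stringsAsFactors = FALSE
      )
    }
    recs <- if (both_survey) {
      rbind(mk_rec("standard"), mk_rec("nonstandard"))
    } else if (nonstd_survey) {
      mk_rec("nonstandard")
    } else {
      mk_rec("standard")
    }
    out[[s]] <- recs
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  class(obs) <- c("observation_set", "data.frame")
  validate_observations(obs)
  obs
}

#' Validate an observation set
#'
#' Checks the binomial contract (0 <= k <= N, N >= 1) and that every record
#' carries a resolvable point or polygon reference.
#'
#' @param obs An observation data frame.
#' @return `obs`, invisibly; errors on violation.
#' @export
validate_observations <- function(obs) {
  need <- c("survey_id", "year", "geo_type", "cell_id", "polygon_id",
            "N", "k", "indicator", "definition")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation set missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(obs$N < 1L)) stop("all denominators N must be >= 1", call. = FALSE)
  if (any(obs$k < 0L | obs$k > obs$N))
    stop("k must satisfy 0 <= k <= N", call. = FALSE)
  pt <- obs$geo_type == "point"
  if (any(pt & is.na(obs$cell_id)) || any(!pt & is.na(obs$polygon_id)))
    stop("point records need cell_id; polygon records need polygon_id",
         call. = FALSE)
  invisible(obs)
}

#' Simulate a diarrhoeal mortality surface linked to ORS coverage
#'
#' Deaths per cell-year are `pop * base_rate * (1 - epsilon * ors_coverage)`,
#' optionally perturbed by multiplicative log-normal noise, so mortality is
#' negatively associated with coverage by construction.
#'
#' @param ors_truth ORS coverage truth [raster_cube()].
#' @param pop Population [raster_cube()].
#' @param link List with `base_rate` (> 0, deaths per child per year, default
#'   0.002) and `epsilon` (in \[0, 1), default 0.6), optional `noise_sd`
#'   (log-scale sd, default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A single-layer [raster_cube()] named `deaths`.
#' @export
simulate_mortality <- function(ors_truth, pop, link = list(), seed = 1L) {
  l <- utils::modifyList(list(base_rate = 0.002, epsilon = 0.6, noise_sd = 0),
                         link)
  if (l$base_rate <= 0) stop("base_rate must be > 0", call. = FALSE)
  if (l$epsilon < 0 || l$epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  p <- cube_layer(ors_truth, "p")
  w <- cube_layer(pop, 1L)
  deaths <- w * l$base_rate * (1 - l$epsilon * p)
  if (l$noise_sd > 0) {
    set.seed(seed)
    deaths <- deaths * exp(matrix(stats::rnorm(length(deaths),
                                               sd = l$noise_sd),
                                  nrow(deaths)))
  }
  raster_cube(pmax(deaths, 0), ors_truth$grid, "deaths")
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper producing every input the pipeline consumes: grid,
#' covariates, population, per-indicator truth surfaces (with ORT defined as
#' treatment with ORS or RHF under independence,
#' `p_ORT = 1 - (1 - p_ORS)(1 - p_RHF)`, so ORT coverage always dominates
#' ORS coverage cell-wise), surveys per indicator, a diarrhoea-episodes
#' raster (population times episode prevalence) and a mortality raster
#' linked to ORS coverage.
#'
#' @param grid A [grid_spec()] (default desk-scale 30x30, 6 years).
#' @param indicators Subset of `c("ORS", "RHF", "ORT")`.
#' @param params Named list of [truth_params()] per indicator; defaults give
#'   ORS a rising and RHF a falling trend with moderate spatial structure.
#' @param survey_design Passed to [simulate_surveys()]; RHF surveys get
#'   `nonstandard_fraction = 0.35` unless overridden.
#' @param episode_prev Diarrhoea-episode prevalence among children under 5
#'   (default 0.2).
#' @param mortality_link Passed to [simulate_mortality()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return List of class `synthetic_world` with elements `grid`, `covariates`,
#'   `population`, `truth` (list per indicator), `observations` (list per
#'   indicator), `episodes`, `mortality`, `seed`.
#' @export
simulate_world <- function(grid = grid_spec(),
                           indicators = c("ORS", "RHF", "ORT"),
                           params = NULL,
                           survey_design = list(),
                           episode_prev = 0.2,
                           mortality_link = list(),
                           seed = 1L) {
  indicators <- match.arg(indicators, c("ORS", "RHF", "ORT"),
                          several.ok = TRUE)
  seed <- as.integer(seed)
  covs <- simulate_covariates(grid, seed = seed + 11L)
  pop <- simulate_population(grid, seed = seed + 13L)
  n_layers <- dim(covs$values)[3L]
  default_beta <- c(0.6, -0.4, 0.3, rep(0, n_layers - 3L))
  if (is.null(params)) {
    params <- list(
      ORS = truth_params(alpha = -0.6, beta = default_beta, sigma2_sp = 0.4,
                         range_sp = 8, rho_t = 0.8, tau2_nugget = 0.05,
                         trend = 0.08),
      RHF = truth_params(alpha = -1.0, beta = -0.5 * default_beta,
                         sigma2_sp = 0.4, range_sp = 8, rho_t = 0.8,
                         tau2_nugget = 0.05, trend = -0.08)
    )
  }
  truth <- list()
  need_parts <- "ORT" %in% indicators
  for (ind in c("ORS", "RHF")) {
    if (ind %in% indicators || need_parts)
      truth[[ind]] <- simulate_truth(grid, covs, params[[ind]], ind,
                                     seed = seed + match(ind, c("ORS", "RHF")))
  }
  if (need_parts) {
    p_ort <- 1 - (1 - cube_layer(truth$ORS, "p")) *
      (1 - cube_layer(truth$RHF, "p"))
    truth$ORT <- raster_cube(p_ort, grid, "p")
    attr(truth$ORT, "indicator") <- "ORT"
    attr(truth$ORT, "tau2_nugget") <- params$ORS$tau2_nugget
  }
  truth <- truth[intersect(c("ORS", "RHF", "ORT"), indicators)]

  observations <- list()
  for (ind in indicators) {
    des <- survey_design
    if (ind == "RHF" && is.null(des$nonstandard_fraction))
      des$nonstandard_fraction <- 0.35
    observations[[ind]] <- simulate_surveys(truth[[ind]], pop, des,
                                            seed = seed + 100L +
                                              match(ind, c("ORS", "RHF", "ORT")))
  }
  episodes <- raster_cube(cube_layer(pop, 1L) * episode_prev, grid, "episodes")
  mortality <- if ("ORS" %in% names(truth))
    simulate_mortality(truth$ORS, pop, mortality_link, seed = seed + 31L)
  else NULL

  structure(list(grid = grid, covariates = covs, population = pop,
                 truth = truth, observations = observations,
                 episodes = episodes, mortality = mortality, seed = seed),
            class = "synthetic_world")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
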