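# Bayesian space-time binomial geostatistical model ("mbg" = model-based
# geostatistics). Latent structure:
#
#   k_i ~ Binomial(N_i, p_i),   logit(p_i) = x_i' beta + t_i
#   t = A u + e,   u ~ GP(0, sigma2 * Matern32(range) x AR1(rho)),
#   e ~ N(0, tau2 I)   (cluster-level nugget)
#
# A maps records to the latent field: a point record selects its cell-year;
# a polygon record averages member cells with population weights (on the
# linear-predictor scale inside the fit; the standalone log_likelihood()
# aggregates on the probability scale as the data-generating story states).
#
# Inference: Laplace approximation of the latent posterior at fixed
# hyperparameters; hyperparameters (log sigma2, log range, atanh rho,
# log tau2) estimated by maximizing the Laplace-approximate marginal
# posterior, with posterior uncertainty from a Gaussian approximation at the
# mode (numerical Hessian). Joint coverage-surface draws mix latent draws
# over sampled hyperparameter configurations and extend them to the full
# grid by conditional simulation (conditioning by kriging). An elliptical
# slice sampling MCMC backend is available via mbg_spec(method = "mcmc").

#' Priors for the geostatistical model
#'
#' Weakly-informative Gaussian priors on transformed hyperparameters and on
#' the fixed effects. Defaults: `log(sigma2) ~ N(log 0.5, 1.5^2)`,
#' `log(range) ~ N(log 8, 1^2)` (cell units), `atanh(rho) ~ N(0.55, 1^2)`
#' (centred near rho = 0.5), `log(tau2) ~ N(log 0.05, 1.5^2)`, and
#' `beta ~ N(0, 10^2)` independently.
#'
#' @param sigma2,range,rho,tau2 Each a `c(mean, sd)` pair on the transformed
#'   scale.
#' @param beta_sd Prior standard deviation of fixed effects.
#' @return List of class `mbg_priors`.
#' @export
mbg_priors <- function(sigma2 = c(log(0.5), 1.5), range = c(log(8), 1),
                       rho = c(0.55, 1), tau2 = c(log(0.05), 1.5),
                       beta_sd = 10) {
  structure(list(sigma2 = sigma2, range = range, rho = rho, tau2 = tau2,
                 beta_sd = beta_sd), class = "mbg_priors")
}

#' Model specification for [mbg()]
#'
#' @param method Inference engine: `"laplace"` (default; Laplace
#'   approximation with Gaussian hyperparameter mixing) or `"mcmc"`
#'   (elliptical slice sampling on the latent field with random-walk
#'   Metropolis on hyperparameters).
#' @param priors An [mbg_priors()] object.
#' @param n_hyper Number of hyperparameter configurations mixed into the
#'   posterior (Laplace method).
#' @param optim_maxit Nelder-Mead iteration cap for the hyperparameter mode
#'   search.
#' @param max_newton Newton iteration cap for the inner latent optimization.
#' @param fix_theta Optional named vector `c(sigma2_sp=, range_sp=, rho_t=,
#'   tau2_nugget=)` fixing hyperparameters (skips the mode search;
#'   useful for speed-sensitive refits).
#' @param mcmc List of MCMC controls: `n_iter` (2000), `burnin` (500),
#'   `thin` (5), `prop_sd` (0.15).
#' @param region Optional region identifier recorded in the fit.
#' @return List of class `mbg_spec`.
#' @export
mbg_spec <- function(method = c("laplace", "mcmc"), priors = mbg_priors(),
                     n_hyper = 15L, optim_maxit = 150L, max_newton = 40L,
                     fix_theta = NULL, mcmc = list(), region = NA) {
  method <- match.arg(method)
  mcmc <- utils::modifyList(list(n_iter = 2000L, burnin = 500L, thin = 5L,
                                 prop_sd = 0.15), mcmc)
  structure(list(method = method, priors = priors, n_hyper = n_hyper,
                 optim_maxit = optim_maxit, max_newton = max_newton,
                 fix_theta = fix_theta, mcmc = mcmc, region = region),
            class = "mbg_spec")
}

# transformed <-> natural hyperparameters
theta_to_natural <- function(th) {
  c(sigma2_sp = exp(th[1L]), range_sp = exp(th[2L]),
    rho_t = min(max(tanh(th[3L]), -1 + 1e-8), 1 - 1e-8),
    tau2_nugget = exp(th[4L]))
}
natural_to_theta <- function(nat) {
  c(log(nat[["sigma2_sp"]]), log(nat[["range_sp"]]), atanh(nat[["rho_t"]]),
    log(nat[["tau2_nugget"]]))
}

log_prior_theta <- function(th, priors) {
  stats::dnorm(th[1L], priors$sigma2[1L], priors$sigma2[2L], log = TRUE) +
    stats::dnorm(th[2L], priors$range[1L], priors$range[2L], log = TRUE) +
    stats::dnorm(th[3L], priors$rho[1L], priors$rho[2L], log = TRUE) +
    stats::dnorm(th[4L], priors$tau2[1L], priors$tau2[2L], log = TRUE)
}

# --- data preparation --------------------------------------------------

# Build the record-to-field mapping. Returns:
#   d_cell, d_year_idx: the D distinct cell-years touched
#   map: per record, list(idx = positions into D, w = weights)
#   point_d: for pure point records, the single D position (NA for polygons)
# plus factored covariance structure: distinct cells with scaled pairwise
# distances (Matern is evaluated once per cell pair, AR1 looked up by year
# lag) and deduplicated record profiles (records sharing a cell-year or a
# polygon-year have identical field functionals).
build_mapping <- function(obs, grid, pop) {
  yr_idx <- match(obs$year, grid$years)
  if (anyNA(yr_idx)) stop("observation year outside grid years", call. = FALSE)
  mem <- grid$membership
  keys <- character(0)
  rec_keys <- vector("list", nrow(obs))
  rec_w <- vector("list", nrow(obs))
  pop_mat <- if (!is.null(pop)) cube_layer(pop, 1L) else NULL
  for (i in seq_len(nrow(obs))) {
    if (obs$geo_type[i] == "point") {
      cid <- obs$cell_id[i]
      if (cid < 0L || cid >= grid$n_cells)
        stop("record references missing cell ", cid, call. = FALSE)
      rec_keys[[i]] <- paste0(cid, "_", yr_idx[i])
      rec_w[[i]] <- 1
    } else {
      cells <- mem$cell_id[mem$admin1_id == obs$polygon_id[i]]
      if (!length(cells))
        stop("polygon id ", obs$polygon_id[i], " resolves to no cells",
             call. = FALSE)
      if (is.null(pop_mat))
        stop("polygon records require a population raster", call. = FALSE)
      w <- pop_mat[cells + 1L, yr_idx[i]]
      if (sum(w) <= 0)
        stop("polygon id ", obs$polygon_id[i], " has zero population",
             call. = FALSE)
      rec_keys[[i]] <- paste0(cells, "_", yr_idx[i])
      rec_w[[i]] <- w / sum(w)
    }
  }
  all_keys <- unique(unlist(rec_keys))
  parts <- do.call(rbind, strsplit(all_keys, "_", fixed = TRUE))
  d_cell <- as.integer(parts[, 1L])
  d_year_idx <- as.integer(parts[, 2L])
  map <- lapply(seq_len(nrow(obs)), function(i)
    list(idx = match(rec_keys[[i]], all_keys), w = rec_w[[i]]))
  point_d <- vapply(map, function(m)
    if (length(m$idx) == 1L) m$idx else NA_integer_, integer(1))

  # factored covariance structure
  cells_u <- sort(unique(d_cell))
  Uc <- sqrt(3) * as.matrix(stats::dist(grid$coords[cells_u + 1L, ,
                                                    drop = FALSE]))
  ci_D <- match(d_cell, cells_u)
  # record profiles: unique field functionals
  prof_key <- vapply(seq_len(nrow(obs)), function(i) {
    if (obs$geo_type[i] == "point") paste0("p", point_d[i])
    else paste0("g", obs$polygon_id[i], "_", yr_idx[i])
  }, character(1))
  keys_u <- unique(prof_key)
  pid <- match(prof_key, keys_u)
  profiles <- lapply(keys_u, function(kk) {
    i <- which(prof_key == kk)[1L]
    m <- map[[i]]
    list(is_point = obs$geo_type[i] == "point", d_idx = m$idx, w = m$w,
         cell_i = ci_D[m$idx], t = yr_idx[i])
  })
  list(d_cell = d_cell, d_year_idx = d_year_idx, map = map,
       point_d = point_d, yr_idx = yr_idx,
       cells_u = cells_u, Uc = Uc, ci_D = ci_D,
       profiles = profiles, pid = pid, n_years = length(grid$years))
}

# K = A Sigma_D A' + tau2 I via the factored structure: Matern over
# distinct cells, AR1 by year lag, profiles deduplicated.
cov_K <- function(mp, nat) {
  u <- mp$Uc / nat[["range_sp"]]
  Ms <- (1 + u) * exp(-u)
  Rt <- nat[["rho_t"]]^abs(outer(seq_len(mp$n_years), seq_len(mp$n_years),
                                 "-"))
  npf <- length(mp$profiles)
  Dn <- length(mp$d_cell)
  P <- matrix(NA_real_, npf, Dn)  # profile x D field covariances
  is_pt <- vapply(mp$profiles, `[[`, logical(1), "is_point")
  if (any(is_pt)) {
    rc <- vapply(mp$profiles[is_pt], `[[`, integer(1), "cell_i")
    rt <- vapply(mp$profiles[is_pt], `[[`, integer(1), "t")
    P[is_pt, ] <- Ms[rc, mp$ci_D, drop = FALSE] *
      Rt[rt, mp$d_year_idx, drop = FALSE]
  }
  for (j in which(!is_pt)) {
    pf <- mp$profiles[[j]]
    v <- as.numeric(crossprod(Ms[pf$cell_i, , drop = FALSE], pf$w))
    P[j, ] <- v[mp$ci_D] * Rt[pf$t, mp$d_year_idx]
  }
  Q <- matrix(NA_real_, npf, npf)
  if (any(is_pt)) {
    dpos <- vapply(mp$profiles[is_pt], `[[`, integer(1), "d_idx")
    Q[, is_pt] <- P[, dpos, drop = FALSE]
  }
  for (j in which(!is_pt)) {
    pf <- mp$profiles[[j]]
    Q[, j] <- as.numeric(P[, pf$d_idx, drop = FALSE] %*% pf$w)
  }
  Q <- nat[["sigma2_sp"]] * (Q + t(Q)) / 2
  K <- Q[mp$pid, mp$pid, drop = FALSE]
  diag(K) <- diag(K) + nat[["tau2_nugget"]]
  K
}

# --- Laplace approximation at fixed hyperparameters --------------------

# Maximizes loglik(eta) - 0.5 g' Qp g over g = (beta, t); eta = X beta + t.
# Returns the mode, its chol(H), and the Laplace log marginal (up to const).
laplace_fit <- function(k, N, X, K, beta_sd, max_newton = 40L, g0 = NULL) {
  n <- length(k); p <- ncol(X)
  cK <- chol_jitter(K)
  Kinv <- chol2inv(cK)
  logdetK <- 2 * sum(log(diag(cK)))
  g <- if (is.null(g0)) {
    p_emp <- (sum(k) + 0.5) / (sum(N) + 1)
    c(stats::qlogis(p_emp), rep(0, p - 1L), rep(0, n))
  } else g0
  obj <- function(g) {
    beta <- g[seq_len(p)]; t_ <- g[-seq_len(p)]
    eta <- as.numeric(X %*% beta) + t_
    pr <- stats::plogis(eta)
    ll <- sum(k * eta - N * log1p(exp(eta)))
    ll - 0.5 * sum(beta^2) / beta_sd^2 -
      0.5 * as.numeric(crossprod(t_, Kinv %*% t_))
  }
  f <- obj(g)
  cH <- NULL
  for (it in seq_len(max_newton)) {
    beta <- g[seq_len(p)]; t_ <- g[-seq_len(p)]
    eta <- as.numeric(X %*% beta) + t_
    pr <- stats::plogis(eta)
    u <- k - N * pr
    W <- pmax(N * pr * (1 - pr), 1e-10)
    grad <- c(as.numeric(crossprod(X, u)) - beta / beta_sd^2,
              u - as.numeric(Kinv %*% t_))
    XW <- X * W
    H <- rbind(cbind(crossprod(X, XW) + diag(1 / beta_sd^2, p), t(XW)),
               cbind(XW, Kinv + diag(W)))
    cH <- chol_jitter(H)
    step <- backsolve(cH, forwardsolve(t(cH), grad))
    sl <- 1
    repeat {
      g_new <- g + sl * step
      f_new <- obj(g_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      sl <- sl / 2
      if (sl < 1e-6) { g_new <- g; f_new <- f; break }
    }
    done <- max(abs(g_new - g)) < 1e-6 || abs(f_new - f) < 1e-9
    g <- g_new; f <- f_new
    if (done) break
  }
  # final Hessian at the mode
  beta <- g[seq_len(p)]; t_ <- g[-seq_len(p)]
  eta <- as.numeric(X %*% beta) + t_
  pr <- stats::plogis(eta)
  W <- pmax(N * pr * (1 - pr), 1e-10)
  XW <- X * W
  H <- rbind(cbind(crossprod(X, XW) + diag(1 / beta_sd^2, p), t(XW)),
             cbind(XW, Kinv + diag(W)))
  cH <- chol_jitter(H)
  logml <- f - 0.5 * logdetK - p * log(beta_sd) - sum(log(diag(cH)))
  list(g = g, cholH = cH, cK = cK, Kinv = Kinv, logml = logml,
       eta = eta, iters = it)
}

#' Fit the space-time binomial geostatistical model
#'
#' Fits a hierarchical logistic regression with a separable Matern 3/2
#' (space) x AR1 (time) latent Gaussian field and a cluster-level nugget to
#' binomial survey records. Point records tie to their cell-year; polygon
#' records tie to the population-weighted mean over their admin1 cells.
#' See [mbg_spec()] for the inference engines.
#'
#' @param obs An `observation_set` (one indicator; definitions already
#'   crosswalked).
#' @param grid A [grid_spec()].
#' @param design Optional fixed-effect design beyond the intercept: list with
#'   `obs` (numeric vector or n x q matrix, e.g. stacker predictions on the
#'   logit scale) and `grid` (cell x year matrix or cell x year x q array
#'   giving the same covariates on the prediction grid).
#' @param pop Population [raster_cube()]; required when `obs` contains
#'   polygon records.
#' @param spec An [mbg_spec()].
#' @param seed Integer seed (hyperparameter sampling / MCMC).
#' @return Object of class `mbg` with methods [print.mbg()], [summary.mbg()],
#'   [coef.mbg()], [fitted.mbg()], [residuals.mbg()], [predict.mbg()],
#'   [simulate.mbg()], [plot.mbg()]; draw surfaces with
#'   [draw_posterior_surfaces()].
#' @export
mbg <- function(obs, grid, design = NULL, pop = NULL, spec = mbg_spec(),
                seed = 1L) {
  if (is.null(obs) || nrow(obs) == 0L)
    stop("empty observation set", call. = FALSE)
  validate_observations(obs)
  stopifnot(inherits(grid, "grid_spec"), inherits(spec, "mbg_spec"))
  set.seed(seed)

  X <- matrix(1, nrow(obs), 1L, dimnames = list(NULL, "(Intercept)"))
  Xg <- NULL
  if (!is.null(design)) {
    Xo <- as.matrix(design$obs)
    if (nrow(Xo) != nrow(obs)) stop("design/obs mismatch", call. = FALSE)
    if (is.null(colnames(Xo))) colnames(Xo) <- sprintf("f%d", seq_len(ncol(Xo)))
    X <- cbind(X, Xo)
    Xg <- design$grid
    if (is.matrix(Xg)) Xg <- array(Xg, c(dim(Xg), 1L))
    if (is.null(Xg) || dim(Xg)[3L] != ncol(Xo))
      stop("design$grid must carry one layer per design column",
           call. = FALSE)
  }
  mp <- build_mapping(obs, grid, pop)
  pr <- spec$priors

  if (spec$method == "laplace") {
    g_warm <- NULL  # warm-start the inner Newton across objective calls
    neg_obj <- function(th, g0 = g_warm) {
      nat <- theta_to_natural(th)
      K <- cov_K(mp, nat)
      lp <- laplace_fit(obs$k, obs$N, X, K, pr$beta_sd, spec$max_newton, g0)
      g_warm <<- lp$g
      -(lp$logml + log_prior_theta(th, pr))
    }
    if (!is.null(spec$fix_theta)) {
      th_hat <- natural_to_theta(spec$fix_theta)
      Sig_th <- diag(1e-12, 4L)
      opt_conv <- 0L
    } else {
      th0 <- c(log(0.3), log(max(grid$n_rows, grid$n_cols) / 4), atanh(0.5),
               log(0.05))
      opt <- stats::optim(th0, neg_obj, method = "Nelder-Mead",
                          control = list(maxit = spec$optim_maxit,
                                         reltol = 1e-5))
      th_hat <- opt$par
      opt_conv <- opt$convergence
      # numerical Hessian -> Gaussian approx of the hyper posterior
      h <- 0.08
      H4 <- matrix(NA_real_, 4L, 4L)
      f0 <- opt$value
      fp <- fm <- numeric(4L)
      for (a in 1:4) {
        ea <- rep(0, 4L); ea[a] <- h
        fp[a] <- neg_obj(th_hat + ea); fm[a] <- neg_obj(th_hat - ea)
        H4[a, a] <- (fp[a] - 2 * f0 + fm[a]) / h^2
      }
      for (a in 1:3) for (b in (a + 1):4) {
        ea <- rep(0, 4L); ea[a] <- h
        eb <- rep(0, 4L); eb[b] <- h
        fpp <- neg_obj(th_hat + ea + eb)
        fmm <- neg_obj(th_hat - ea - eb)
        H4[a, b] <- H4[b, a] <-
          (fpp - fp[a] - fp[b] + 2 * f0 - fm[a] - fm[b] + fmm) / (2 * h^2)
      }
      eg <- eigen((H4 + t(H4)) / 2, symmetric = TRUE)
      # floor curvature at roughly the prior information so a flat marginal
      # yields prior-scale (not unbounded) hyperparameter uncertainty
      ev <- pmax(eg$values, 0.4)
      Sig_th <- eg$vectors %*% diag(1 / ev, 4L) %*% t(eg$vectors)
    }
    nat_hat <- theta_to_natural(th_hat)
    K <- cov_K(mp, nat_hat)
    mode_state <- laplace_fit(obs$k, obs$N, X, K, pr$beta_sd, spec$max_newton)
    if (!is.finite(mode_state$logml))
      stop("non-convergence: non-finite Laplace marginal at the mode",
           call. = FALSE)

    # sample hyperparameter configurations and refit the latent mode at each
    R_th <- chol_jitter(Sig_th)
    n_h <- max(1L, spec$n_hyper)
    hyper <- vector("list", n_h)
    for (s in seq_len(n_h)) {
      th_s <- if (s == 1L) th_hat else
        th_hat + as.numeric(t(R_th) %*% stats::rnorm(4L))
      nat_s <- theta_to_natural(th_s)
      K_s <- cov_K(mp, nat_s)
      lp <- laplace_fit(obs$k, obs$N, X, K_s, pr$beta_sd, spec$max_newton,
                        g0 = mode_state$g)
      hyper[[s]] <- list(theta = th_s, nat = nat_s, g = lp$g,
                         cholH = lp$cholH, cK = lp$cK)
    }
    fit <- list(method = "laplace", obs = obs, grid = grid, X = X,
                design_grid = Xg, mapping = mp, spec = spec, seed = seed,
                theta_mode = th_hat, nat_mode = nat_hat, theta_vcov = Sig_th,
                hyper = hyper, mode_state = mode_state,
                logml = mode_state$logml,
                convergence = list(optim = opt_conv,
                                   newton_iters = mode_state$iters))
  } else {
    fit <- mbg_fit_mcmc(obs, grid, X, Xg, mp, spec, seed)
  }
  class(fit) <- "mbg"
  fit
}

# --- MCMC backend: elliptical slice sampling on g, RW Metropolis on theta
mbg_fit_mcmc <- function(obs, grid, X, Xg, mp, spec, seed) {
  pr <- spec$priors
  n <- nrow(obs); p <- ncol(X)
  k <- obs$k; N <- obs$N
  ctl <- spec$mcmc
  loglik <- function(g) {
    eta <- as.numeric(X %*% g[seq_len(p)]) + g[-seq_len(p)]
    sum(k * eta - N * log1p(exp(eta)))
  }
  th <- c(log(0.3), log(max(grid$n_rows, grid$n_cols) / 4), atanh(0.5),
          log(0.05))
  nat <- theta_to_natural(th)
  K <- cov_K(mp, nat)
  cK <- chol_jitter(K)
  g <- c(rep(0, p), rep(0, n))
  draw_prior <- function(cK) {
    c(stats::rnorm(p, 0, pr$beta_sd), as.numeric(t(cK) %*% stats::rnorm(n)))
  }
  log_prior_g <- function(g, cK) {
    t_ <- g[-seq_len(p)]
    v <- forwardsolve(t(cK), t_)
    -sum(log(diag(cK))) - 0.5 * sum(v^2) -
      0.5 * sum(g[seq_len(p)]^2) / pr$beta_sd^2
  }
  keep <- list()
  ll <- loglik(g)
  n_iter <- ctl$n_iter
  for (it in seq_len(n_iter)) {
    # elliptical slice sampling for g under its Gaussian prior
    nu <- draw_prior(cK)
    u <- log(stats::runif(1))
    thr <- ll + u
    ang <- stats::runif(1, 0, 2 * pi)
    lo <- ang - 2 * pi; hi <- ang
    repeat {
      g_prop <- g * cos(ang) + nu * sin(ang)
      ll_prop <- loglik(g_prop)
      if (ll_prop > thr) break
      if (ang < 0) lo <- ang else hi <- ang
      ang <- stats::runif(1, lo, hi)
      if (hi - lo < 1e-10) { g_prop <- g; ll_prop <- ll; break }
    }
    g <- g_prop; ll <- ll_prop
    # Metropolis update of transformed hyperparameters
    th_prop <- th + stats::rnorm(4L, sd = ctl$prop_sd)
    nat_prop <- theta_to_natural(th_prop)
    K_p <- cov_K(mp, nat_prop)
    cK_p <- tryCatch(chol_jitter(K_p), error = function(e) NULL)
    if (!is.null(cK_p)) {
      la <- log_prior_g(g, cK_p) + log_prior_theta(th_prop, pr) -
        log_prior_g(g, cK) - log_prior_theta(th, pr)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        th <- th_prop; cK <- cK_p
      }
    }
    if (it > ctl$burnin && (it - ctl$burnin) %% ctl$thin == 0L) {
      keep[[length(keep) + 1L]] <-
        list(theta = th, nat = theta_to_natural(th), g = g, cholH = NULL,
             cK = cK)
    }
  }
  if (!length(keep)) stop("MCMC produced no retained samples", call. = FALSE)
  th_mat <- do.call(rbind, lapply(keep, `[[`, "theta"))
  list(method = "mcmc", obs = obs, grid = grid, X = X, design_grid = Xg,
       mapping = mp, spec = spec, seed = seed,
       theta_mode = colMeans(th_mat),
       nat_mode = theta_to_natural(colMeans(th_mat)),
       theta_vcov = stats::cov(th_mat), hyper = keep,
       mode_state = list(g = keep[[length(keep)]]$g,
                         eta = as.numeric(X %*% keep[[length(keep)]]$g[seq_len(ncol(X))]) +
                           keep[[length(keep)]]$g[-seq_len(ncol(X))],
                         iters = spec$mcmc$n_iter),
       logml = NA_real_, convergence = list(optim = 0L))
}

#' Binomial log likelihood of a coverage surface
#'
#' Sums binomial log-probabilities of the records given a coverage
#' probability surface. Point records use the probability at their
#' cell-year; polygon records use the population-weighted mean probability
#' over their admin1's cells, matching the data-generating story for
#' polygon-referenced surveys.
#'
#' @param p_surface A [raster_cube()] of probabilities, or a cell x year
#'   matrix aligned to `grid`.
#' @param obs An `observation_set`.
#' @param grid A [grid_spec()] (taken from the cube when omitted).
#' @param pop Population [raster_cube()]; required for polygon records.
#' @return Total log likelihood (scalar).
#' @export
log_likelihood <- function(p_surface, obs, grid = NULL, pop = NULL) {
  if (inherits(p_surface, "raster_cube")) {
    grid <- p_surface$grid
    p_mat <- cube_layer(p_surface, 1L)
  } else p_mat <- as.matrix(p_surface)
  validate_observations(obs)
  yr_idx <- match(obs$year, grid$years)
  if (anyNA(yr_idx)) stop("record year outside surface years", call. = FALSE)
  mem <- grid$membership
  pop_mat <- if (!is.null(pop)) cube_layer(pop, 1L) else NULL
  ll <- 0
  for (i in seq_len(nrow(obs))) {
    if (obs$geo_type[i] == "point") {
      cid <- obs$cell_id[i]
      if (cid < 0L || cid >= grid$n_cells || is.na(p_mat[cid + 1L, yr_idx[i]]))
        stop("record references missing cell ", cid, call. = FALSE)
      p <- p_mat[cid + 1L, yr_idx[i]]
    } else {
      cells <- mem$cell_id[mem$admin1_id == obs$polygon_id[i]]
      if (is.null(pop_mat))
        stop("polygon records require a population raster", call. = FALSE)
      w <- pop_mat[cells + 1L, yr_idx[i]]
      p <- sum(w * p_mat[cells + 1L, yr_idx[i]]) / sum(w)
    }
    ll <- ll + stats::dbinom(obs$k[i], obs$N[i], p, log = TRUE)
  }
  ll
}
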