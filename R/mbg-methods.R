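# S3 methods for "mbg" fits, and the joint posterior surface draws.

# draws of the fixed effects, mixing over hyperparameter states
fixef_draws <- function(fit, n = 500L) {
  p <- ncol(fit$X)
  K <- length(fit$hyper)
  per <- ceiling(n / K)
  out <- matrix(NA_real_, per * K, p, dimnames = list(NULL, colnames(fit$X)))
  r <- 1L
  for (st in fit$hyper) {
    for (j in seq_len(per)) {
      if (is.null(st$cholH)) {
        out[r, ] <- st$g[seq_len(p)]
      } else {
        z <- stats::rnorm(length(st$g))
        out[r, ] <- (st$g + backsolve(st$cholH, z))[seq_len(p)]
      }
      r <- r + 1L
    }
  }
  out
}

# hyperparameter posterior summary on the natural scale
hyper_summary <- function(fit) {
  if (fit$method == "mcmc") {
    th <- do.call(rbind, lapply(fit$hyper, `[[`, "theta"))
    nat <- t(apply(th, 1L, theta_to_natural))
    data.frame(
      parameter = colnames(nat),
      mean = colMeans(nat),
      lower95 = apply(nat, 2L, stats::quantile, 0.025),
      upper95 = apply(nat, 2L, stats::quantile, 0.975),
      row.names = NULL
    )
  } else {
    sds <- sqrt(pmax(diag(fit$theta_vcov), 0))
    lo <- fit$theta_mode - 1.96 * sds
    hi <- fit$theta_mode + 1.96 * sds
    data.frame(
      parameter = names(theta_to_natural(fit$theta_mode)),
      mean = unname(theta_to_natural(fit$theta_mode)),
      lower95 = unname(theta_to_natural(lo)),
      upper95 = unname(theta_to_natural(hi)),
      row.names = NULL
    )
  }
}

#' @method print mbg
#' @export
print.mbg <- function(x, ...) {
  cat(sprintf("mbg fit (%s): %d records, %d fixed effect(s)\n",
              x$method, nrow(x$obs), ncol(x$X)))
  cat("hyperparameters (posterior mode, natural scale):\n")
  print(round(theta_to_natural(x$theta_mode), 4))
  invisible(x)
}

#' Summarize an mbg fit
#'
#' @param object An `mbg` fit.
#' @param n_fixef_draws Monte Carlo draws for the fixed-effect intervals.
#' @param ... Unused.
#' @return List of class `summary.mbg` with `fixed` and `hyper` tables.
#' @method summary mbg
#' @export
summary.mbg <- function(object, n_fixef_draws = 500L, ...) {
  bd <- fixef_draws(object, n_fixef_draws)
  fixed <- data.frame(
    term = colnames(object$X),
    mean = colMeans(bd),
    lower95 = apply(bd, 2L, stats::quantile, 0.025),
    upper95 = apply(bd, 2L, stats::quantile, 0.975),
    row.names = NULL
  )
  structure(list(fixed = fixed, hyper = hyper_summary(object),
                 method = object$method, n = nrow(object$obs)),
            class = "summary.mbg")
}

#' @method print summary.mbg
#' @export
print.summary.mbg <- function(x, ...) {
  cat(sprintf("mbg fit (%s), %d records\n\nFixed effects:\n", x$method, x$n))
  print(transform(x$fixed, mean = round(mean, 4),
                  lower95 = round(lower95, 4), upper95 = round(upper95, 4)))
  cat("\nHyperparameters:\n")
  print(transform(x$hyper, mean = round(mean, 4),
                  lower95 = round(lower95, 4), upper95 = round(upper95, 4)))
  invisible(x)
}

#' @export
coef.mbg <- function(object, ...) {
  p <- ncol(object$X)
  co <- rowMeans(matrix(vapply(object$hyper,
                               function(st) st$g[seq_len(p)], numeric(p)),
                        nrow = p))
  stats::setNames(co, colnames(object$X))
}

#' @export
fitted.mbg <- function(object, ...) {
  stats::plogis(object$mode_state$eta)
}

#' @export
residuals.mbg <- function(object, ...) {
  object$obs$k / object$obs$N - fitted(object)
}

#' Joint posterior draws of the coverage surface
#'
#' Produces `n_draws` coherent coverage surfaces on the full grid (every
#' draw is one jointly sampled field, not a set of marginal resamples).
#' Each draw picks a hyperparameter configuration, samples the record-level
#' latent state from its conditional Gaussian, and extends it to all grid
#' cell-years by conditional simulation (an unconditional separable-field
#' draw corrected by kriging on the record residuals).
#'
#' @param fit An `mbg` fit.
#' @param n_draws Number of joint draws (default 250; must be >= 2).
#' @param seed Integer seed; same seed, same cube.
#' @return Object of class `draw_cube`: `p` (cell x year x draw array of
#'   probabilities in (0,1)), `grid`, `n_draws`.
#' @export
draw_posterior_surfaces <- function(fit, n_draws = 250L, seed = 1L) {
  stopifnot(inherits(fit, "mbg"))
  if (n_draws < 2L) stop("n_draws must be >= 2", call. = FALSE)
  set.seed(seed)
  grid <- fit$grid
  mp <- fit$mapping
  n_cells <- grid$n_cells
  n_t <- length(grid$years)
  n <- nrow(fit$obs)
  p_fe <- ncol(fit$X)
  G <- n_cells * n_t
  Dn <- length(mp$d_cell)

  # fixed-effect design on the grid, flattened year-block-wise
  Xg_flat <- matrix(1, G, p_fe)
  if (p_fe > 1L) {
    for (q in seq_len(p_fe - 1L))
      Xg_flat[, q + 1L] <- as.numeric(fit$design_grid[, , q])
  }
  dist_grid <- as.matrix(stats::dist(grid$coords))
  cross_cells <- dist_grid[, mp$d_cell + 1L, drop = FALSE]  # n_cells x D
  pt <- !is.na(mp$point_d)

  s_idx <- sample.int(length(fit$hyper), n_draws, replace = TRUE)
  cube <- array(NA_real_, c(n_cells, n_t, n_draws))
  for (s in unique(s_idx)) {
    st <- fit$hyper[[s]]
    nat <- st$nat
    R_s <- chol_jitter(matern32(dist_grid, nat[["range_sp"]]))
    R_t <- chol_jitter(ar1_cor(n_t, nat[["rho_t"]]))
    # Cov(u_G, u_D): year blocks stacked to match as.numeric(cell x year)
    C_cells <- nat[["sigma2_sp"]] * matern32(cross_cells, nat[["range_sp"]])
    M_GD <- matrix(NA_real_, G, Dn)
    for (t in seq_len(n_t)) {
      rows <- (t - 1L) * n_cells + seq_len(n_cells)
      M_GD[rows, ] <- C_cells *
        rep(nat[["rho_t"]]^abs(t - mp$d_year_idx), each = n_cells)
    }
    # Cov(u_G, t) = M_GD A'
    M <- matrix(0, G, n)
    if (any(pt)) M[, pt] <- M_GD[, mp$point_d[pt], drop = FALSE]
    for (j in which(!pt))
      M[, j] <- as.numeric(M_GD[, mp$map[[j]]$idx, drop = FALSE] %*%
                             mp$map[[j]]$w)
    tau <- sqrt(nat[["tau2_nugget"]])
    for (d in which(s_idx == s)) {
      g_star <- if (is.null(st$cholH)) st$g else
        st$g + backsolve(st$cholH, stats::rnorm(length(st$g)))
      beta_star <- g_star[seq_len(p_fe)]
      t_star <- g_star[-seq_len(p_fe)]
      Z <- matrix(stats::rnorm(n_cells * n_t), n_cells, n_t)
      U <- sqrt(nat[["sigma2_sp"]]) * (t(R_s) %*% Z %*% R_t)
      u_D <- U[cbind(mp$d_cell + 1L, mp$d_year_idx)]
      t_unc <- numeric(n)
      if (any(pt)) t_unc[pt] <- u_D[mp$point_d[pt]]
      for (j in which(!pt))
        t_unc[j] <- sum(mp$map[[j]]$w * u_D[mp$map[[j]]$idx])
      t_unc <- t_unc + stats::rnorm(n, sd = tau)
      resid <- t_star - t_unc
      v <- backsolve(st$cK, forwardsolve(t(st$cK), resid))
      u_cond <- as.numeric(U) + as.numeric(M %*% v)
      eta <- as.numeric(Xg_flat %*% beta_star) + u_cond
      cube[, , d] <- matrix(pmin(pmax(stats::plogis(eta), 1e-9), 1 - 1e-9),
                            n_cells, n_t)
    }
  }
  structure(list(p = cube, grid = grid, n_draws = n_draws),
            class = "draw_cube")
}

#' @method print draw_cube
#' @export
print.draw_cube <- function(x, ...) {
  cat(sprintf("draw_cube: %d cells x %d years x %d draws\n",
              dim(x$p)[1L], dim(x$p)[2L], x$n_draws))
  invisible(x)
}

#' Simulate posterior coverage surfaces from an mbg fit
#'
#' Alias for [draw_posterior_surfaces()] following the [stats::simulate()]
#' generic: `nsim` joint surface draws.
#'
#' @param object An `mbg` fit.
#' @param nsim Number of draws (default 250).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A `draw_cube`.
#' @export
simulate.mbg <- function(object, nsim = 250L, seed = 1L, ...) {
  draw_posterior_surfaces(object, n_draws = nsim, seed = seed)
}

#' Predict coverage surfaces from an mbg fit
#'
#' @param object An `mbg` fit.
#' @param type `"mean"` for the posterior-mean surface (cell x year matrix),
#'   `"draws"` for the full [draw_posterior_surfaces()] cube.
#' @param n_draws Draws behind the estimate (default 100 for the mean).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix or `draw_cube` according to `type`.
#' @export
predict.mbg <- function(object, type = c("mean", "draws"), n_draws = 100L,
                        seed = 1L, ...) {
  type <- match.arg(type)
  cube <- draw_posterior_surfaces(object, n_draws = n_draws, seed = seed)
  if (type == "draws") return(cube)
  apply(cube$p, c(1L, 2L), mean)
}

#' Plot observed versus fitted proportions for an mbg fit
#'
#' @param x An `mbg` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mbg <- function(x, ...) {
  obs_p <- x$obs$k / x$obs$N
  graphics::plot(fitted(x), obs_p, xlab = "fitted coverage",
                 ylab = "observed proportion", xlim = c(0, 1),
                 ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
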