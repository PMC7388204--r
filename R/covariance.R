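#' Matern (smoothness 3/2) spatial correlation
#'
#' `cor(d) = (1 + sqrt(3) d / range) exp(-sqrt(3) d / range)`, so the
#' correlation falls to about 0.05 at one range. This is the spatial half of
#' the separable space-time covariance used throughout: Matern 3/2 in space
#' times first-order autoregressive (AR1) in time.
#'
#' @param d Nonnegative distances (cell units).
#' @param range Spatial range parameter (> 0).
#' @return Correlations in (0, 1].
#' @export
matern32 <- function(d, range) {
  stopifnot(range > 0)
  u <- sqrt(3) * d / range
  (1 + u) * exp(-u)
}

# AR1 correlation matrix over the year index
ar1_cor <- function(n_years, rho) {
  stopifnot(abs(rho) < 1)
  outer(seq_len(n_years), seq_len(n_years), function(i, j) rho^abs(i - j))
}

# Cholesky with escalating jitter; returns upper-triangular R with R'R = S
chol_jitter <- function(S, max_tries = 6L) {
  jit <- 0
  for (i in seq_len(max_tries)) {
    R <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-8 * mean(diag(S)) else jit * 10
  }
  stop("covariance matrix is not positive definite", call. = FALSE)
}

# Simulate one draw of a separable Matern32 x AR1 field over the grid.
# Returns an n_cells x n_years matrix with covariance
# sigma2 * matern32(dist) (space) kron ar1 (time).
# R_s may be precomputed (chol of the spatial correlation) and reused.
sim_st_field <- function(grid, sigma2, range_sp, rho_t, R_s = NULL) {
  n_t <- length(grid$years)
  if (sigma2 <= 0) return(matrix(0, grid$n_cells, n_t))
  if (is.null(R_s)) {
    D <- as.matrix(stats::dist(grid$coords))
    R_s <- chol_jitter(matern32(D, range_sp))
  }
  R_t <- chol_jitter(ar1_cor(n_t, rho_t))
  Z <- matrix(stats::rnorm(grid$n_cells * n_t), grid$n_cells, n_t)
  sqrt(sigma2) * (t(R_s) %*% Z %*% R_t)
}
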