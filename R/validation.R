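# Admin2-blocked five-fold cross-validation with the four summary metrics:
# bias (mean error), RMSE, 95% data coverage within posterior-predictive
# intervals, and correlation between observed proportions and predictions.

#' Admin2-blocked cross-validation folds
#'
#' All records sharing a second-administrative unit land in the same fold
#' (point records via their cell's admin2; polygon records via their
#' admin1's first admin2). Units are assigned to folds greedily by
#' descending record count onto the currently smallest fold, after a seeded
#' shuffle, balancing fold sizes.
#'
#' @param obs An `observation_set`.
#' @param grid A [grid_spec()] providing the membership.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id per record (1..k).
#' @export
make_folds <- function(obs, grid, k = 5L, seed = 1L) {
  validate_observations(obs)
  mem <- grid$membership
  unit <- integer(nrow(obs))
  pt <- obs$geo_type == "point"
  unit[pt] <- mem$admin2_id[match(obs$cell_id[pt], mem$cell_id)]
  if (any(!pt)) {
    a1_first_a2 <- tapply(mem$admin2_id, mem$admin1_id, min)
    unit[!pt] <- a1_first_a2[as.character(obs$polygon_id[!pt])]
  }
  tab <- table(unit)
  if (length(tab) < k)
    stop("fewer admin2 units with data (", length(tab), ") than folds (",
         k, ")", call. = FALSE)
  set.seed(seed)
  ids <- sample(names(tab))
  ids <- ids[order(-tab[ids])]
  fold_of_unit <- stats::setNames(integer(length(ids)), ids)
  sizes <- numeric(k)
  for (id in ids) {
    f <- which.min(sizes)
    fold_of_unit[id] <- f
    sizes[f] <- sizes[f] + tab[[id]]
  }
  unname(fold_of_unit[as.character(unit)])
}

#' Cross-validation metrics for held-out records
#'
#' Residuals are observed proportion minus posterior-mean predicted
#' coverage. Reports bias (mean error), RMSE (total variance), 95% data
#' coverage — the share of records whose observed count `k` falls inside
#' the 2.5-97.5 percentile interval of the binomial posterior predictive
#' (coverage draws pushed through `Binomial(N, p)`) — and the Pearson
#' correlation between observed proportions and predictions (unweighted by
#' default; `weight_r = TRUE` weights by `N`).
#'
#' @param obs Held-out `observation_set`.
#' @param p_draws n_records x n_draws matrix of predicted coverage draws at
#'   the records' cell-years.
#' @param weight_r Use N-weighted correlation?
#' @param seed Seed for the binomial predictive draws.
#' @return List of class `cv_metrics`: `bias`, `rmse`, `coverage95`,
#'   `pearson_r`, `n`, `residuals`.
#' @export
cv_metrics <- function(obs, p_draws, weight_r = FALSE, seed = 1L) {
  stopifnot(nrow(p_draws) == nrow(obs))
  set.seed(seed)
  p_hat <- rowMeans(p_draws)
  y <- obs$k / obs$N
  resid <- y - p_hat
  bias <- mean(resid)
  rmse <- sqrt(mean(resid^2))
  n_d <- ncol(p_draws)
  inside <- vapply(seq_len(nrow(obs)), function(i) {
    k_pred <- stats::rbinom(n_d, obs$N[i], p_draws[i, ])
    q <- stats::quantile(k_pred, c(0.025, 0.975), type = 7)
    obs$k[i] >= q[1L] && obs$k[i] <= q[2L]
  }, logical(1))
  r <- if (stats::sd(y) == 0 || stats::sd(p_hat) == 0) {
    warning("zero-variance observations or predictions: r undefined",
            call. = FALSE)
    NA_real_
  } else if (weight_r) {
    w <- obs$N / sum(obs$N)
    my <- sum(w * y); mp <- sum(w * p_hat)
    sum(w * (y - my) * (p_hat - mp)) /
      sqrt(sum(w * (y - my)^2) * sum(w * (p_hat - mp)^2))
  } else stats::cor(y, p_hat)
  structure(list(bias = bias, rmse = rmse, coverage95 = mean(inside),
                 pearson_r = r, n = nrow(obs), residuals = resid),
            class = "cv_metrics")
}

#' @method print cv_metrics
#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(
    "cv_metrics (n=%d): bias %.4f, rmse %.4f, coverage95 %.3f, r %.3f\n",
    x$n, x$bias, x$rmse, x$coverage95, x$pearson_r))
  invisible(x)
}

# predicted coverage draws at each record's cell-year (polygon records:
# population-weighted mean over admin1 cells)
predict_at_records <- function(cube, obs, pop = NULL) {
  grid <- cube$grid
  yr_idx <- match(obs$year, grid$years)
  n_d <- dim(cube$p)[3L]
  P <- matrix(NA_real_, nrow(obs), n_d)
  mem <- grid$membership
  pop_mat <- if (!is.null(pop)) cube_layer(pop, 1L) else NULL
  for (i in seq_len(nrow(obs))) {
    if (obs$geo_type[i] == "point") {
      P[i, ] <- cube$p[obs$cell_id[i] + 1L, yr_idx[i], ]
    } else {
      cells <- mem$cell_id[mem$admin1_id == obs$polygon_id[i]] + 1L
      w <- pop_mat[cells, yr_idx[i]]; w <- w / sum(w)
      P[i, ] <- as.numeric(crossprod(cube$p[cells, yr_idx[i], ], w))
    }
  }
  P
}

#' Admin2-blocked k-fold cross-validation of the geostatistical model
#'
#' Refits the model on each training split and evaluates [cv_metrics()] on
#' the held-out records; stacker out-of-fold designs, being already
#' cross-fitted, are subset rather than refitted. Pooled metrics recompute
#' bias/RMSE over all records (so pooled RMSE^2 equals the record-weighted
#' mean of fold RMSE^2) and pool the coverage indicator.
#'
#' @param obs An `observation_set`.
#' @param grid A [grid_spec()].
#' @param design Optional fixed-effect design as in [mbg()].
#' @param pop Population [raster_cube()].
#' @param k Number of folds (default 5).
#' @param spec An [mbg_spec()] used for each fold fit.
#' @param n_draws Posterior draws per fold for the predictive intervals.
#' @param seed Integer seed.
#' @return List of class `cv_report`: `fold` (assignment), `per_fold`
#'   (list of `cv_metrics`), `pooled` (`cv_metrics` over all records).
#' @export
cross_validate <- function(obs, grid, design = NULL, pop = NULL, k = 5L,
                           spec = mbg_spec(), n_draws = 100L, seed = 1L) {
  fold <- make_folds(obs, grid, k, seed)
  p_draws_all <- matrix(NA_real_, nrow(obs), n_draws)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    des_f <- if (!is.null(design)) {
      Xo <- as.matrix(design$obs)
      list(obs = Xo[tr, , drop = FALSE], grid = design$grid)
    } else NULL
    fit <- mbg(obs[tr, ], grid, design = des_f, pop = pop, spec = spec,
               seed = seed + f)
    cube <- draw_posterior_surfaces(fit, n_draws = n_draws, seed = seed + f)
    P <- predict_at_records(cube, obs[!tr, ], pop)
    p_draws_all[!tr, ] <- P
    per_fold[[f]] <- cv_metrics(obs[!tr, ], P, seed = seed + f)
  }
  pooled <- cv_metrics(obs, p_draws_all, seed = seed)
  structure(list(fold = fold, per_fold = per_fold, pooled = pooled),
            class = "cv_report")
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat("admin2-blocked cross-validation\npooled: ")
  print(x$pooled)
  invisible(x)
}
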