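# Stacked generalisation: flexible child learners are cross-fitted on the
# survey records; their out-of-fold (OOF) predictions become covariates for
# the geostatistical model, capturing non-linear covariate-coverage
# relationships without putting them inside the latent-field fit.

# Feature matrix for records: covariate values at the record's cell-year
# (population-weighted over admin1 cells for polygon records), plus cell
# coordinates and the year (polygon records get the population-weighted
# centroid).
obs_features <- function(obs, covs, pop, layers = NULL) {
  grid <- covs$grid
  if (is.null(layers)) layers <- covs$layers
  pop_mat <- cube_layer(pop, 1L)
  mem <- grid$membership
  yr_idx <- match(obs$year, grid$years)
  n <- nrow(obs)
  F <- matrix(NA_real_, n, length(layers) + 3L,
              dimnames = list(NULL, c(layers, "x", "y", "year")))
  for (i in seq_len(n)) {
    t <- yr_idx[i]
    if (obs$geo_type[i] == "point") {
      c1 <- obs$cell_id[i] + 1L
      F[i, seq_along(layers)] <- covs$values[c1, t, layers]
      F[i, c("x", "y")] <- grid$coords[c1, ]
    } else {
      m <- mem$cell_id[mem$admin1_id == obs$polygon_id[i]] + 1L
      w <- pop_mat[m, t]; w <- w / sum(w)
      M <- matrix(covs$values[m, t, layers, drop = FALSE], nrow = length(m))
      F[i, seq_along(layers)] <- as.numeric(crossprod(M, w))
      F[i, c("x", "y")] <- c(sum(w * grid$coords[m, 1L]),
                             sum(w * grid$coords[m, 2L]))
    }
    F[i, "year"] <- obs$year[i]
  }
  F
}

# Feature matrix for all cell-years of the grid (row blocks by year)
grid_features <- function(covs, layers = NULL) {
  grid <- covs$grid
  if (is.null(layers)) layers <- covs$layers
  n_t <- length(grid$years)
  blocks <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    blocks[[t]] <- cbind(covs$values[, t, layers, drop = TRUE],
                         grid$coords, grid$years[t])
  }
  F <- do.call(rbind, blocks)
  colnames(F) <- c(layers, "x", "y", "year")
  F
}

clip_logit <- function(p, eps = 1e-4) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# --- individual learners -----------------------------------------------
# Each returns function(newX) -> probability predictions, or signals an error.

fit_learner_ridge <- function(X, k, N) {
  foldid <- sample(rep_len(1:5, nrow(X)))
  cv <- glmnet::cv.glmnet(X, cbind(N - k, k), family = "binomial",
                          alpha = 0, foldid = foldid)
  function(newX) {
    as.numeric(stats::predict(cv, newX, s = "lambda.min", type = "response"))
  }
}

fit_learner_gam <- function(X, k, N) {
  df <- as.data.frame(X)
  covn <- setdiff(colnames(X), c("x", "y", "year"))
  kk <- max(4L, min(25L, floor(nrow(X) / 10)))
  terms <- c(sprintf("s(%s, k = 4)", covn), sprintf("s(x, y, k = %d)", kk))
  if (length(unique(df$year)) > 2L) terms <- c(terms, "year")
  f <- stats::as.formula(paste("cbind(k, N - k) ~", paste(terms, collapse = " + ")))
  df$k <- k; df$N <- N
  # select/gamma: extra shrinkage so null-signal data yields a flat fit
  fit <- mgcv::gam(f, family = stats::binomial(), data = df, method = "REML",
                   select = TRUE, gamma = 1.4)
  function(newX) {
    as.numeric(mgcv::predict.gam(fit, as.data.frame(newX), type = "response"))
  }
}

fit_learner_gbt <- function(X, k, N, max_rounds = 200L, max_depth = 2L) {
  bs <- sum(k) / sum(N)  # base score at the pooled mean, so zero boosting
  # rounds reduce to the pooled-proportion predictor
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = 0.1, nthread = 1, subsample = 1,
                 min_child_weight = 50, lambda = 2, base_score = bs)
  dtr <- xgboost::xgb.DMatrix(X, label = k / N, weight = N)
  # round count by small internal CV (weighted logloss, early stopping):
  # noise-only data stops almost immediately, structured data keeps going
  idx <- sample(rep_len(1:3, nrow(X)))
  cv <- xgboost::xgb.cv(params = params, data = dtr, nrounds = max_rounds,
                        folds = lapply(1:3, function(f) which(idx == f)),
                        early_stopping_rounds = 15L, verbose = 0)
  best <- which.min(cv$evaluation_log$test_logloss_mean)
  fit <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = max(best, 1L), verbose = 0)
  function(newX) as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(newX)))
}

#' Fit stacked-generalisation child learners with cross-fitting
#'
#' Fits three learners of increasing flexibility on the binomial records —
#' ridge-penalized logistic regression (`glmnet`), a smooth additive model on
#' covariates and coordinates (`mgcv`), and boosted depth-2 regression trees
#' (`xgboost`) — using k-fold cross-fitting so each record's out-of-fold
#' prediction never saw that record, plus a full-data fit used to predict
#' each learner's surface on the whole grid. Predictions are clipped to the
#' logit of \[1e-4, 1 - 1e-4\].
#'
#' @param obs An `observation_set` (adjusted to the standard definition).
#' @param covs Covariate [raster_cube()] (typically the VIF-retained layers).
#' @param pop Population [raster_cube()] (for polygon feature aggregation).
#' @param k_folds Number of cross-fitting folds (default 5).
#' @param layers Covariate layers to use (default all in `covs`).
#' @param seed Integer seed controlling fold assignment and learner
#'   stochasticity.
#' @return Object of class `stacker_bundle`: `learners` (names), `oof`
#'   (n x L matrix of OOF predictions, logit scale), `grid_pred`
#'   (cell x year x L array, logit scale), `fold` (per-record fold id),
#'   `features` (record feature matrix), `seed`.
#' @export
fit_child_learners <- function(obs, covs, pop, k_folds = 5L, layers = NULL,
                               seed = 1L) {
  validate_observations(obs)
  n <- nrow(obs)
  if (n < k_folds) stop("fewer records than folds", call. = FALSE)
  set.seed(seed)
  X <- obs_features(obs, covs, pop, layers)
  Xg <- grid_features(covs, layers)
  fold <- sample(rep_len(seq_len(k_folds), n))
  fitters <- list(ridge = fit_learner_ridge, gam = fit_learner_gam,
                  gbt = fit_learner_gbt)
  oof <- matrix(NA_real_, n, length(fitters),
                dimnames = list(NULL, names(fitters)))
  grid_pred <- array(NA_real_,
                     c(covs$grid$n_cells, length(covs$grid$years),
                       length(fitters)))
  ok <- logical(length(fitters)); names(ok) <- names(fitters)
  for (l in seq_along(fitters)) {
    name <- names(fitters)[l]
    res <- tryCatch({
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        pred <- fitters[[l]](X[tr, , drop = FALSE], obs$k[tr], obs$N[tr])
        oof[!tr, l] <- clip_logit(pred(X[!tr, , drop = FALSE]))
      }
      full <- fitters[[l]](X, obs$k, obs$N)
      grid_pred[, , l] <- matrix(clip_logit(full(Xg)), covs$grid$n_cells)
      TRUE
    }, error = function(e) {
      warning(sprintf("learner '%s' failed and was dropped: %s", name,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    ok[l] <- res
  }
  if (!any(ok)) stop("all child learners failed", call. = FALSE)
  structure(list(learners = names(fitters)[ok],
                 oof = oof[, ok, drop = FALSE],
                 grid_pred = grid_pred[, , ok, drop = FALSE],
                 fold = fold, features = X, grid = covs$grid, seed = seed),
            class = "stacker_bundle")
}

#' @method print stacker_bundle
#' @export
print.stacker_bundle <- function(x, ...) {
  cat(sprintf("stacker_bundle: %d learner(s) [%s], %d records, %d folds\n",
              length(x$learners), paste(x$learners, collapse = ", "),
              nrow(x$oof), length(unique(x$fold))))
  invisible(x)
}

#' Assemble the stacked design for the geostatistical model
#'
#' Observation rows carry each learner's out-of-fold prediction (logit
#' scale); the prediction grid carries the corresponding full-data learner
#' surfaces. Column order is the bundle's learner order.
#'
#' @param bundle A `stacker_bundle`.
#' @return List with `X_obs` (n x L, logit scale), `X_grid`
#'   (cell x year x L array), `learners`.
#' @export
stack_design <- function(bundle) {
  stopifnot(inherits(bundle, "stacker_bundle"))
  if (anyNA(bundle$grid_pred)) stop("missing learner raster", call. = FALSE)
  list(X_obs = bundle$oof, X_grid = bundle$grid_pred,
       learners = bundle$learners)
}

#' Estimate convex stacking weights on out-of-fold predictions
#'
#' Finds non-negative, sum-to-one weights over the child learners minimizing
#' the out-of-fold binomial deviance of `plogis(OOF %*% w)` (softmax
#' parameterization, quasi-Newton optimization). These weights implement the
#' convex-combination ensembling constraint.
#'
#' @param bundle A `stacker_bundle`.
#' @param obs The `observation_set` the bundle was fitted on.
#' @return Named weight vector (non-negative, sums to 1).
#' @export
stack_weights <- function(bundle, obs) {
  L <- ncol(bundle$oof)
  if (L == 1L) return(stats::setNames(1, colnames(bundle$oof)))
  dev <- function(theta) {
    w <- exp(c(0, theta)); w <- w / sum(w)
    p <- stats::plogis(as.numeric(bundle$oof %*% w))
    -sum(stats::dbinom(obs$k, obs$N, pmin(pmax(p, 1e-9), 1 - 1e-9),
                       log = TRUE))
  }
  opt <- stats::optim(rep(0, L - 1L), dev, method = "BFGS",
                      control = list(maxit = 200))
  w <- exp(c(0, opt$par)); w <- w / sum(w)
  stats::setNames(w, colnames(bundle$oof))
}

# Collapse a stacked design to the single convex-combination covariate
# (logit scale) used as fixed effect by mbg(): returns list(obs, grid).
combine_stackers <- function(design, weights) {
  obs_logit <- as.numeric(design$X_obs %*% weights)
  dims <- dim(design$X_grid)
  grid_logit <- matrix(0, dims[1L], dims[2L])
  for (l in seq_along(weights))
    grid_logit <- grid_logit + weights[l] * design$X_grid[, , l]
  list(obs = obs_logit, grid = grid_logit)
}
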