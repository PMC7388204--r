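#' Variance inflation factors of a covariate design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column `j` on
#' all other columns (with intercept). Exact collinearity yields an `Inf`
#' sentinel rather than an error.
#'
#' @param X Numeric matrix (rows = cell-year observations, columns = layers)
#'   with at least 2 columns and more rows than columns.
#' @return Named numeric vector of VIFs, one per column.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite values in design", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Iteratively filter covariates by variance inflation factor
#'
#' Greedy backward elimination: while any VIF exceeds the threshold, drop the
#' single worst column and recompute. The study design this mirrors filters
#' for multicollinearity within each modelling region with a VIF threshold
#' of 3; run this once per region on that region's pooled cell-year values.
#' Ties at the maximum VIF are broken by removing the lexicographically
#' first column name.
#'
#' @param X Numeric matrix as in [compute_vif()].
#' @param threshold VIF threshold (default 3).
#' @param region Optional region identifier recorded in the report.
#' @return Object of class `vif_report`: `retained` (column names), `vif`
#'   (final VIFs of retained columns), `removed` (data frame of removal
#'   order, name, and the VIF at removal), `threshold`, `region`.
#' @export
vif_filter <- function(X, threshold = 3, region = NA) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  removed <- data.frame(order = integer(), layer = character(),
                        vif = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) == 0L)
      stop("all columns removed by VIF filtering", call. = FALSE)
    if (ncol(X) == 1L) {
      vif <- stats::setNames(1, colnames(X))  # single survivor by convention
      break
    }
    vif <- compute_vif(X)
    if (all(vif <= threshold)) break
    worst <- max(vif)
    cand <- sort(names(vif)[vif == worst])[1L]
    removed <- rbind(removed,
                     data.frame(order = nrow(removed) + 1L, layer = cand,
                                vif = worst, stringsAsFactors = FALSE))
    X <- X[, setdiff(colnames(X), cand), drop = FALSE]
  }
  structure(list(retained = colnames(X), vif = vif, removed = removed,
                 threshold = threshold, region = region),
            class = "vif_report")
}

#' @method print vif_report
#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF filter (threshold %.3g%s): retained %d layer(s)\n",
              x$threshold,
              if (!is.na(x$region)) paste0(", region ", x$region) else "",
              length(x$retained)))
  print(round(x$vif, 3))
  if (nrow(x$removed))
    cat("removed:", paste(x$removed$layer, collapse = " > "), "\n")
  invisible(x)
}
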