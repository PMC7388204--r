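# Population-weighted aggregation of posterior draw cubes to administrative
# units, uncertainty intervals, annualised rates of change, untreated-child
# counts and trend correlations.

#' Summarize posterior draws into mean and 95% uncertainty interval
#'
#' The uncertainty interval is the 2.5th and 97.5th empirical percentiles of
#' the draws, computed with the linear-interpolation percentile rule
#' ([stats::quantile()] type 7).
#'
#' @param draws Numeric vector of posterior draws (>= 2, no NaN).
#' @return Named vector `c(mean, lower95, upper95)`.
#' @export
summarize_ui <- function(draws) {
  if (length(draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (anyNA(draws)) stop("NaN/NA draws", call. = FALSE)
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(draws), lower95 = q[1L], upper95 = q[2L])
}

#' Population-weighted aggregation of a draw cube to admin units
#'
#' For each posterior draw and year, a unit's value is the
#' population-weighted mean of its member cells,
#' `sum(pop_i p_i) / sum(pop_i)`. Units with zero population are dropped
#' with a warning.
#'
#' @param cube A `draw_cube` (or a truth [raster_cube()], treated as one
#'   degenerate draw plus a duplicate so intervals are defined).
#' @param pop Population [raster_cube()].
#' @param level `"admin2"`, `"admin1"` or `"country"`.
#' @param membership Optional membership data frame (defaults to the grid's).
#' @return Object of class `admin_aggregate`: `draws` (unit x year x draw
#'   array), `summary` (data frame `unit_id, level, year, mean, lower95,
#'   upper95`), `units`, `years`, `level`, `pop_totals` (unit x year).
#' @export
aggregate_draws <- function(cube, pop, level = c("admin2", "admin1",
                                                 "country"),
                            membership = NULL) {
  level <- match.arg(level)
  if (inherits(cube, "raster_cube")) {
    p <- cube_layer(cube, 1L)
    cube <- structure(list(p = array(rep(p, 2L), c(dim(p), 2L)),
                           grid = cube$grid, n_draws = 2L),
                      class = "draw_cube")
  }
  grid <- cube$grid
  mem <- membership %||% grid$membership
  col <- paste0(sub("country", "country", level), "_id")
  unit_of_cell <- mem[[col]][match(0:(grid$n_cells - 1L), mem$cell_id)]
  units <- sort(unique(unit_of_cell))
  pop_mat <- cube_layer(pop, 1L)
  n_t <- dim(cube$p)[2L]; n_d <- dim(cube$p)[3L]

  pop_tot <- rowsum(pop_mat, unit_of_cell)           # unit x year
  keep <- rowSums(pop_tot) > 0
  if (!all(keep)) {
    warning("excluding unit(s) with zero population: ",
            paste(rownames(pop_tot)[!keep], collapse = ", "), call. = FALSE)
  }
  agg <- array(NA_real_, c(length(units), n_t, n_d))
  for (d in seq_len(n_d)) {
    wp <- rowsum(pop_mat * cube$p[, , d], unit_of_cell)
    agg[, , d] <- wp / pop_tot
  }
  agg <- agg[keep, , , drop = FALSE]
  units <- units[keep]
  pop_tot <- pop_tot[keep, , drop = FALSE]

  sm <- do.call(rbind, lapply(seq_along(units), function(i) {
    do.call(rbind, lapply(seq_len(n_t), function(t) {
      s <- summarize_ui(agg[i, t, ])
      data.frame(unit_id = units[i], level = level, year = grid$years[t],
                 mean = s[["mean"]], lower95 = s[["lower95"]],
                 upper95 = s[["upper95"]])
    }))
  }))
  rownames(sm) <- NULL
  structure(list(draws = agg, summary = sm, units = units,
                 years = grid$years, level = level, pop_totals = pop_tot),
            class = "admin_aggregate")
}

#' @method print admin_aggregate
#' @export
print.admin_aggregate <- function(x, ...) {
  cat(sprintf("admin_aggregate (%s): %d units x %d years x %d draws\n",
              x$level, length(x$units), length(x$years), dim(x$draws)[3L]))
  invisible(x)
}

#' Annualised rate of change of coverage between two years
#'
#' Computed per posterior draw on the logit scale,
#' `AROC_d = (logit(p_y1,d) - logit(p_y0,d)) / (y1 - y0)`, reported in
#' percent; the summary attaches the 95% UI and a significance flag (UI
#' excludes 0). Probabilities at 0 or 1 are clipped to
#' `[1e-6, 1 - 1e-6]` with a warning. A log-ratio formula
#' (`(log p1 - log p0) / dy`) is available via `scale = "log"`.
#'
#' @param agg An `admin_aggregate`.
#' @param y0,y1 Start and end years (`y0 < y1`, both present).
#' @param scale `"logit"` (default) or `"log"`.
#' @return Data frame per unit: `unit_id, mean, lower95, upper95,
#'   significant`, plus the draw matrix as attribute `"draws"`.
#' @export
compute_aroc <- function(agg, y0, y1, scale = c("logit", "log")) {
  scale <- match.arg(scale)
  i0 <- match(y0, agg$years); i1 <- match(y1, agg$years)
  if (is.na(i0) || is.na(i1) || y0 >= y1)
    stop("need y0 < y1, both present in the aggregate", call. = FALSE)
  p0 <- agg$draws[, i0, , drop = TRUE]
  p1 <- agg$draws[, i1, , drop = TRUE]
  if (is.null(dim(p0))) { p0 <- matrix(p0, 1L); p1 <- matrix(p1, 1L) }
  if (any(p0 <= 0 | p0 >= 1 | p1 <= 0 | p1 >= 1)) {
    warning("probabilities at 0/1 clipped to [1e-6, 1-1e-6]", call. = FALSE)
    p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
    p1 <- pmin(pmax(p1, 1e-6), 1 - 1e-6)
  }
  f <- if (scale == "logit") stats::qlogis else log
  ar <- 100 * (f(p1) - f(p0)) / (y1 - y0)
  out <- do.call(rbind, lapply(seq_along(agg$units), function(i) {
    s <- summarize_ui(ar[i, ])
    data.frame(unit_id = agg$units[i], mean = s[["mean"]],
               lower95 = s[["lower95"]], upper95 = s[["upper95"]],
               significant = s[["lower95"]] > 0 | s[["upper95"]] < 0)
  }))
  rownames(out) <- NULL
  attr(out, "draws") <- ar
  out
}

#' Count untreated children with uncertainty
#'
#' Per draw, untreated children in a unit-year are
#' `sum over cells of episodes * (1 - p)`; the episodes raster (children
#' with diarrhoea per cell-year) is treated as fixed, so all uncertainty
#' comes from the coverage draws.
#'
#' @param cube A `draw_cube` of treatment coverage (typically ORT).
#' @param episodes [raster_cube()] of diarrhoea episodes (>= 0).
#' @param level Aggregation level.
#' @param year Year to evaluate.
#' @param membership Optional membership override.
#' @return List with `total` (`mean, lower95, upper95`), `per_unit` data
#'   frame, and the per-unit draw matrix as `draws`.
#' @export
count_untreated <- function(cube, episodes, level = "admin2", year,
                            membership = NULL) {
  grid <- cube$grid
  t <- match(year, grid$years)
  if (is.na(t)) stop("year ", year, " not in cube", call. = FALSE)
  ep <- cube_layer(episodes, 1L)[, t]
  if (any(ep < 0)) stop("episodes must be nonnegative", call. = FALSE)
  mem <- membership %||% grid$membership
  unit_of_cell <- mem[[paste0(level, "_id")]][match(0:(grid$n_cells - 1L),
                                                    mem$cell_id)]
  n_d <- dim(cube$p)[3L]
  per <- rowsum(ep * (1 - cube$p[, t, ]), unit_of_cell)  # unit x draw
  units <- as.numeric(rownames(per))
  tot <- colSums(per)
  per_unit <- do.call(rbind, lapply(seq_along(units), function(i) {
    s <- summarize_ui(per[i, ])
    data.frame(unit_id = units[i], mean = s[["mean"]],
               lower95 = s[["lower95"]], upper95 = s[["upper95"]])
  }))
  rownames(per_unit) <- NULL
  list(total = summarize_ui(tot), per_unit = per_unit, draws = per,
       year = year, level = level)
}

#' Share of units whose mean coverage lies below a threshold
#'
#' @param agg An `admin_aggregate` (or its `summary` data frame).
#' @param threshold Coverage threshold (probability scale).
#' @param year Year to evaluate (default: last).
#' @return List `count`, `total`, `pct` (percentage rounded to one decimal).
#' @export
proportion_below <- function(agg, threshold, year = NULL) {
  sm <- if (inherits(agg, "admin_aggregate")) agg$summary else agg
  if (is.null(year)) year <- max(sm$year)
  sm <- sm[sm$year == year, ]
  if (!nrow(sm)) stop("empty aggregate", call. = FALSE)
  count <- sum(sm$mean < threshold)
  total <- nrow(sm)
  list(count = count, total = total, pct = round(100 * count / total, 1))
}

#' Per-unit correlation between two coverage time-series
#'
#' Pearson correlation over years of the two per-unit annual mean series
#' (e.g. ORS vs RHF coverage, or ORS coverage vs mortality rate), plus the
#' share of units with negative correlation. Units with zero variance in
#' either series are excluded from the share's denominator; units with
#' fewer than 3 common years are skipped with a warning.
#'
#' @param series_a,series_b Unit x year matrices with identical dimnames
#'   (rows = unit ids), or `admin_aggregate` objects (their draw means are
#'   used).
#' @return List with `per_unit` (data frame `unit_id, r`), `n_negative`,
#'   `n_assessed`, `share_negative_pct` (1-decimal percentage),
#'   `n_excluded`.
#' @export
correlate_trends <- function(series_a, series_b) {
  to_mat <- function(x) {
    if (inherits(x, "admin_aggregate")) {
      m <- apply(x$draws, c(1L, 2L), mean)
      dimnames(m) <- list(x$units, x$years)
      m
    } else as.matrix(x)
  }
  A <- to_mat(series_a); B <- to_mat(series_b)
  units <- intersect(rownames(A), rownames(B))
  years <- intersect(colnames(A), colnames(B))
  if (length(years) < 3L) {
    warning("fewer than 3 common years; no units assessed", call. = FALSE)
    return(list(per_unit = data.frame(unit_id = character(), r = numeric()),
                n_negative = 0L, n_assessed = 0L,
                share_negative_pct = NA_real_, n_excluded = length(units)))
  }
  r <- vapply(units, function(u) {
    a <- A[u, years]; b <- B[u, years]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }, numeric(1))
  assessed <- !is.na(r)
  list(per_unit = data.frame(unit_id = units, r = unname(r)),
       n_negative = sum(r[assessed] < 0),
       n_assessed = sum(assessed),
       share_negative_pct = round(100 * sum(r[assessed] < 0) /
                                    max(sum(assessed), 1L), 1),
       n_excluded = sum(!assessed))
}
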