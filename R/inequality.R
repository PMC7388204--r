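# Within-country geographical inequality metrics: population-weighted Gini,
# absolute percentage-point deviation from the country mean, relative
# deviation from the country mean, and their trends over the study period.

#' Population-weighted Gini coefficient
#'
#' `G = sum_ij w_i w_j |x_i - x_j| / (2 * weighted.mean(x, w))` with weights
#' normalized to sum to 1: 0 is perfect equality across the population, 1
#' maximal inequality. With equal weights this reduces to the classic
#' unweighted Gini over units.
#'
#' @param values Per-unit coverage values (>= 0, not all zero).
#' @param weights Per-unit population weights (> 0); default equal.
#' @return The Gini coefficient in \[0, 1\].
#' @export
gini <- function(values, weights = NULL) {
  x <- as.numeric(values)
  if (any(x < 0)) stop("values must be nonnegative", call. = FALSE)
  if (all(x == 0)) stop("all values zero: Gini undefined", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x) || any(w <= 0))
    stop("weights must be positive, one per value", call. = FALSE)
  w <- w / sum(w)
  xbar <- sum(w * x)
  sum(outer(w, w) * abs(outer(x, x, "-"))) / (2 * xbar)
}

#' Deviation of unit coverage from the country mean
#'
#' Absolute deviation in percentage points, `100 * (p_unit - p_country)`,
#' and relative deviation in percent of the country mean,
#' `100 * (p_unit - p_country) / p_country`.
#'
#' @param unit_means Named per-unit mean coverage.
#' @param country_mean Population-weighted country mean coverage.
#' @return Data frame `unit_id, abs_dev_pp, rel_dev_pct` (relative deviation
#'   `NA` with a warning when the country mean is zero).
#' @export
deviation_from_mean <- function(unit_means, country_mean) {
  abs_dev <- 100 * (unit_means - country_mean)
  if (country_mean > 0) {
    rel_dev <- 100 * (unit_means - country_mean) / country_mean
  } else {
    warning("zero country mean: relative deviation undefined", call. = FALSE)
    rel_dev <- rep(NA_real_, length(unit_means))
  }
  data.frame(unit_id = names(unit_means) %||% seq_along(unit_means),
             abs_dev_pp = unname(abs_dev), rel_dev_pct = unname(rel_dev))
}

#' Per-country inequality record for one year
#'
#' Computes, for each country, the population-weighted Gini over its admin2
#' units and each unit's absolute / relative deviation from the
#' population-weighted country mean. Uses draw means by default; set
#' `per_draw = TRUE` to obtain a Gini uncertainty interval from the draws.
#'
#' @param agg An `admin_aggregate` at admin2 level.
#' @param membership Membership data frame linking admin2 to country.
#' @param year Year to evaluate.
#' @param per_draw Also compute per-draw Gini and attach its 95% UI?
#' @return List of class `inequality_record`: `gini` data frame
#'   (`country_id, year, gini`, plus UI columns when `per_draw`),
#'   `deviations` data frame (`country_id, unit_id, year, abs_dev_pp,
#'   rel_dev_pct`).
#' @export
inequality_record <- function(agg, membership, year, per_draw = FALSE) {
  stopifnot(inherits(agg, "admin_aggregate"), agg$level == "admin2")
  t <- match(year, agg$years)
  if (is.na(t)) stop("year not in aggregate", call. = FALSE)
  map <- unique(membership[, c("admin2_id", "country_id")])
  country_of_unit <- map$country_id[match(agg$units, map$admin2_id)]
  pops <- agg$pop_totals[, t]
  means <- apply(agg$draws[, t, , drop = FALSE], 1L, mean)
  gtab <- list(); dtab <- list()
  for (cn in sort(unique(country_of_unit))) {
    i <- which(country_of_unit == cn)
    g <- gini(means[i], pops[i])
    row <- data.frame(country_id = cn, year = year, gini = g)
    if (per_draw) {
      gd <- apply(agg$draws[i, t, , drop = FALSE], 3L,
                  function(v) gini(v, pops[i]))
      s <- summarize_ui(gd)
      row$gini_lower95 <- s[["lower95"]]; row$gini_upper95 <- s[["upper95"]]
    }
    gtab[[length(gtab) + 1L]] <- row
    cmean <- stats::weighted.mean(means[i], pops[i])
    dev <- deviation_from_mean(stats::setNames(means[i], agg$units[i]), cmean)
    dtab[[length(dtab) + 1L]] <-
      data.frame(country_id = cn, unit_id = agg$units[i], year = year,
                 abs_dev_pp = dev$abs_dev_pp, rel_dev_pct = dev$rel_dev_pct)
  }
  structure(list(gini = do.call(rbind, gtab),
                 deviations = do.call(rbind, dtab), year = year),
            class = "inequality_record")
}

#' Inequality trends between two years
#'
#' Per-country change flags between a baseline and a final inequality
#' record: did the Gini decline, did the absolute range (max - min unit
#' deviation) decline, did the maximum relative deviation decline, and does
#' any unit sit at >= 50% relative deviation in the final year; plus
#' cross-country counts with integer-rounded percentages.
#'
#' @param rec0,rec1 `inequality_record`s for the two years (same countries).
#' @return List with `per_country` data frame and `counts` list
#'   (`n_countries`, `gini_declined`, `gini_declined_pct`,
#'   `abs_range_declined`, `max_rel_declined`, `any_rel_dev_ge50`, each
#'   count with a `_pct` companion).
#' @export
inequality_trends <- function(rec0, rec1) {
  c0 <- sort(rec0$gini$country_id); c1 <- sort(rec1$gini$country_id)
  if (!identical(c0, c1)) stop("mismatched country sets", call. = FALSE)
  per <- do.call(rbind, lapply(c0, function(cn) {
    g0 <- rec0$gini$gini[rec0$gini$country_id == cn]
    g1 <- rec1$gini$gini[rec1$gini$country_id == cn]
    d0 <- rec0$deviations[rec0$deviations$country_id == cn, ]
    d1 <- rec1$deviations[rec1$deviations$country_id == cn, ]
    data.frame(
      country_id = cn,
      gini_declined = g1 < g0,
      abs_range_declined = diff(range(d1$abs_dev_pp)) <
        diff(range(d0$abs_dev_pp)),
      max_rel_declined = max(abs(d1$rel_dev_pct)) <
        max(abs(d0$rel_dev_pct)),
      any_rel_dev_ge50 = any(abs(d1$rel_dev_pct) >= 50)
    )
  }))
  n <- nrow(per)
  cnt <- function(v) list(n = sum(v), pct = round(100 * sum(v) / n))
  list(per_country = per,
       counts = list(
         n_countries = n,
         gini_declined = cnt(per$gini_declined)$n,
         gini_declined_pct = cnt(per$gini_declined)$pct,
         abs_range_declined = cnt(per$abs_range_declined)$n,
         abs_range_declined_pct = cnt(per$abs_range_declined)$pct,
         max_rel_declined = cnt(per$max_rel_declined)$n,
         max_rel_declined_pct = cnt(per$max_rel_declined)$pct,
         any_rel_dev_ge50 = cnt(per$any_rel_dev_ge50)$n,
         any_rel_dev_ge50_pct = cnt(per$any_rel_dev_ge50)$pct))
}
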