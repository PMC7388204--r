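# Counterfactual mortality analysis: deaths attributable to lack of ORS and
# deaths averted by coverage change, under a linear effectiveness model
# reduction(c) = epsilon * c. The main scenario calibrates epsilon so that
# 75% coverage reduces diarrhoeal deaths by 69% (epsilon = 0.92); the
# sensitivity scenarios halve and double that effect (the halved scenario
# anchors a 35% reduction at 75% coverage).

#' Effectiveness model for ORS mortality reduction
#'
#' @param scenario `"main"` (epsilon = 0.69/0.75 = 0.92), `"halved"`
#'   (epsilon anchors a 35% reduction at 75% coverage), or `"doubled"`
#'   (twice the main effect, capped just below 1 with a warning since a
#'   reduction fraction cannot reach 1).
#' @return List of class `effectiveness_model` with `epsilon`, `scenario`.
#' @export
effectiveness_model <- function(scenario = c("main", "halved", "doubled")) {
  scenario <- match.arg(scenario)
  eps <- switch(scenario,
                main = 0.69 / 0.75,
                halved = 0.35 / 0.75,
                doubled = 2 * 0.69 / 0.75)
  if (eps >= 1) {
    warning("epsilon capped just below 1 for scenario '", scenario, "'",
            call. = FALSE)
    eps <- 1 - 1e-6
  }
  structure(list(epsilon = eps, scenario = scenario),
            class = "effectiveness_model")
}

#' Fraction of diarrhoeal deaths prevented at a given coverage
#'
#' Linear effectiveness: `reduction(c) = epsilon * c`; at 75% coverage the
#' main scenario returns 0.69 and the halved scenario 0.35.
#'
#' @param c Coverage in \[0, 1\] (vectorized).
#' @param model An [effectiveness_model()].
#' @return Fraction(s) of deaths prevented.
#' @export
reduction_at <- function(c, model = effectiveness_model()) {
  if (any(c < 0 | c > 1)) stop("coverage must lie in [0, 1]", call. = FALSE)
  model$epsilon * c
}

#' Deaths attributable to lack of ORS treatment
#'
#' Observed deaths `D` occurred under coverage `c`; the no-ORS baseline is
#' `D0 = D / (1 - epsilon c)` and the deaths that full coverage would have
#' prevented but lack of treatment did not are
#' `D - D0 (1 - epsilon) = D epsilon (1 - c) / (1 - epsilon c)`.
#'
#' @param D_obs Observed deaths (>= 0, vectorized).
#' @param c_obs Observed coverage in \[0, 1\].
#' @param model An [effectiveness_model()].
#' @return Attributable deaths (>= 0).
#' @export
deaths_attributable <- function(D_obs, c_obs, model = effectiveness_model()) {
  if (any(D_obs < 0)) stop("deaths must be nonnegative", call. = FALSE)
  if (any(c_obs < 0 | c_obs > 1)) stop("coverage must lie in [0, 1]",
                                       call. = FALSE)
  if (any(model$epsilon * c_obs >= 1))
    stop("epsilon * coverage >= 1: baseline deaths undefined", call. = FALSE)
  D_obs * model$epsilon * (1 - c_obs) / (1 - model$epsilon * c_obs)
}

#' Deaths averted by an observed coverage change
#'
#' `averted = D_2017 epsilon (c_1 - c_0) / (1 - epsilon c_1)`: positive when
#' coverage rose (lives saved), negative when it fell (deaths attributable
#' to worsening coverage).
#'
#' @param D_obs Deaths observed in the final year (>= 0).
#' @param c0,c1 Baseline and final coverage in \[0, 1\].
#' @param model An [effectiveness_model()].
#' @return Signed averted deaths.
#' @export
deaths_averted <- function(D_obs, c0, c1, model = effectiveness_model()) {
  if (any(D_obs < 0)) stop("deaths must be nonnegative", call. = FALSE)
  if (any(c0 < 0 | c0 > 1 | c1 < 0 | c1 > 1))
    stop("coverage must lie in [0, 1]", call. = FALSE)
  if (any(model$epsilon * c1 >= 1))
    stop("epsilon * coverage >= 1: baseline deaths undefined", call. = FALSE)
  D_obs * model$epsilon * (c1 - c0) / (1 - model$epsilon * c1)
}

#' Run the counterfactual deaths analysis per admin unit
#'
#' Aggregates the mortality raster to units, then applies
#' [deaths_attributable()] and [deaths_averted()] per unit per posterior
#' coverage draw under each effectiveness scenario; uncertainty intervals
#' come from the draw percentiles and rates are per 1000 children under 5.
#'
#' @param mortality [raster_cube()] of deaths per cell-year.
#' @param ors_agg `admin_aggregate` of ORS coverage draws (same level as the
#'   output).
#' @param pop Population [raster_cube()] (children under 5).
#' @param y0,y1 Baseline and final years.
#' @param scenarios Character subset of `c("main", "halved", "doubled")`.
#' @return Named list per scenario, each a list with `table` (per-unit data
#'   frame `unit_id, deaths_obs, c0_mean, c1_mean, attributable_mean,
#'   attributable_l95, attributable_u95, averted_mean, averted_l95,
#'   averted_u95, averted_per_1000`) and `totals` (attributable and averted
#'   with UIs, summed draw-wise over units).
#' @export
run_counterfactual <- function(mortality, ors_agg, pop, y0, y1,
                               scenarios = c("main", "halved", "doubled")) {
  i0 <- match(y0, ors_agg$years); i1 <- match(y1, ors_agg$years)
  if (is.na(i0) || is.na(i1)) stop("years not in aggregate", call. = FALSE)
  grid <- mortality$grid
  mem <- grid$membership
  unit_of_cell <- mem[[paste0(ors_agg$level, "_id")]][
    match(0:(grid$n_cells - 1L), mem$cell_id)]
  dmat <- cube_layer(mortality, 1L)
  deaths_unit <- rowsum(dmat[, match(y1, grid$years)], unit_of_cell)
  deaths_unit <- deaths_unit[match(ors_agg$units,
                                   as.numeric(rownames(deaths_unit))), 1L]
  pop_unit <- ors_agg$pop_totals[, i1]
  n_d <- dim(ors_agg$draws)[3L]
  out <- list()
  for (sc in scenarios) {
    model <- effectiveness_model(sc)
    att <- avt <- matrix(NA_real_, length(ors_agg$units), n_d)
    for (d in seq_len(n_d)) {
      c0 <- ors_agg$draws[, i0, d]
      c1 <- ors_agg$draws[, i1, d]
      att[, d] <- deaths_attributable(deaths_unit, c1, model)
      avt[, d] <- deaths_averted(deaths_unit, c0, c1, model)
    }
    tab <- do.call(rbind, lapply(seq_along(ors_agg$units), function(i) {
      sa <- summarize_ui(att[i, ]); sv <- summarize_ui(avt[i, ])
      data.frame(unit_id = ors_agg$units[i],
                 deaths_obs = deaths_unit[i],
                 c0_mean = mean(ors_agg$draws[i, i0, ]),
                 c1_mean = mean(ors_agg$draws[i, i1, ]),
                 attributable_mean = sa[["mean"]],
                 attributable_l95 = sa[["lower95"]],
                 attributable_u95 = sa[["upper95"]],
                 averted_mean = sv[["mean"]],
                 averted_l95 = sv[["lower95"]],
                 averted_u95 = sv[["upper95"]],
                 averted_per_1000 = 1000 * sv[["mean"]] / pop_unit[i])
    }))
    rownames(tab) <- NULL
    out[[sc]] <- list(table = tab,
                      totals = list(attributable = summarize_ui(colSums(att)),
                                    averted = summarize_ui(colSums(avt))),
                      scenario = sc, epsilon = model$epsilon,
                      draws = list(attributable = att, averted = avt))
  }
  out
}
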