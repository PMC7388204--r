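#' Fit a definition-crosswalk adjustment model
#'
#' Some surveys measure RHF (or other indicators) under a non-standard
#' definition. Surveys reporting the *same* clusters under both the standard
#' and the non-standard definition provide calibration pairs: per survey we
#' pool counts under each definition and fit a binomial-weighted logistic
#' regression of the standard counts on the empirical logit of the
#' non-standard proportion,
#' `logit(p_standard) = intercept + slope * logit(p_nonstandard)`.
#' Empirical logits use a 0.5 continuity correction so boundary proportions
#' stay finite.
#'
#' @param obs An `observation_set` containing at least two surveys that
#'   report both definitions.
#' @return Object of class `adjustment_model`: `intercept`, `slope`,
#'   `n_calibration` (number of paired surveys), `indicator`, and `fallback`
#'   (TRUE when a non-positive fitted slope forced the offset-only model).
#' @export
fit_definition_adjustment <- function(obs) {
  validate_observations(obs)
  std <- obs[obs$definition == "standard", ]
  non <- obs[obs$definition == "nonstandard", ]
  paired <- intersect(unique(std$survey_id), unique(non$survey_id))
  if (length(paired) < 2L)
    stop("no calibration overlap: need >= 2 surveys reporting both ",
         "definitions", call. = FALSE)
  agg <- function(d, ids) {
    d <- d[d$survey_id %in% ids, ]
    k <- tapply(d$k, d$survey_id, sum)[ids]
    N <- tapply(d$N, d$survey_id, sum)[ids]
    cbind(k = k, N = N)
  }
  a_std <- agg(std, paired)
  a_non <- agg(non, paired)
  elogit_non <- log((a_non[, "k"] + 0.5) / (a_non[, "N"] - a_non[, "k"] + 0.5))
  fit <- tryCatch(
    stats::glm(cbind(a_std[, "k"], a_std[, "N"] - a_std[, "k"]) ~ elogit_non,
               family = stats::binomial()),
    error = function(e) stop("degenerate crosswalk fit: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  if (any(!is.finite(co)))
    stop("degenerate crosswalk fit: non-finite coefficients (separation?)",
         call. = FALSE)
  fallback <- FALSE
  if (co[2L] <= 0) {
    # monotonicity guard: fall back to offset-only model (slope fixed at 1)
    warning("fitted crosswalk slope was not positive; ",
            "falling back to offset-only adjustment", call. = FALSE)
    elogit_std <- log((a_std[, "k"] + 0.5) /
                        (a_std[, "N"] - a_std[, "k"] + 0.5))
    w <- a_std[, "N"] + a_non[, "N"]
    co <- c(sum(w * (elogit_std - elogit_non)) / sum(w), 1)
    fallback <- TRUE
  }
  structure(list(intercept = unname(co[1L]), slope = unname(co[2L]),
                 n_calibration = length(paired),
                 indicator = unique(obs$indicator)[1L],
                 fallback = fallback),
            class = "adjustment_model")
}

#' @method print adjustment_model
#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf(
    "definition crosswalk (%s): logit(p_std) = %.4f + %.4f * logit(p_non)\n",
    x$indicator, x$intercept, x$slope))
  cat(sprintf("  calibrated on %d paired surveys%s\n", x$n_calibration,
              if (x$fallback) " [offset-only fallback]" else ""))
  invisible(x)
}

#' Apply a crosswalk adjustment to non-standard records
#'
#' Maps every non-standard record's proportion through the fitted model on
#' the logit scale (continuity-corrected empirical logit in, inverse logit
#' out), replaces `k` by `round(N * p_adjusted)` clamped to `[0, N]`, and
#' retags the record `standard(adjusted)`. Standard records pass through
#' untouched.
#'
#' @param obs An `observation_set`.
#' @param model An `adjustment_model` from [fit_definition_adjustment()].
#' @return The adjusted `observation_set`.
#' @export
apply_adjustment <- function(obs, model) {
  stopifnot(inherits(model, "adjustment_model"))
  validate_observations(obs)
  idx <- which(obs$definition == "nonstandard")
  if (length(idx)) {
    k <- obs$k[idx]; N <- obs$N[idx]
    elogit <- log((k + 0.5) / (N - k + 0.5))
    p_adj <- stats::plogis(model$intercept + model$slope * elogit)
    obs$k[idx] <- as.integer(pmin(pmax(round(N * p_adj), 0), N))
    obs$definition[idx] <- "standard(adjusted)"
  }
  obs
}
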