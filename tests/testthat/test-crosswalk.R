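# paired-survey fixture: n_pairs surveys reporting both definitions, with
# true logit offset and slope relating nonstandard to standard coverage
make_pairs <- function(n_pairs, offset = 0, slope = 1, N_per = 400L,
                       N_non = N_per, seed = 1L) {
  set.seed(seed)
  p_non <- runif(n_pairs, 0.15, 0.85)
  p_std <- plogis(offset + slope * qlogis(p_non))
  rows <- lapply(seq_len(n_pairs), function(s) {
    data.frame(
      survey_id = sprintf("svy_%03d", s), year = 2000L, geo_type = "point",
      cell_id = 0L, polygon_id = NA_integer_,
      N = c(N_per, N_non),
      k = c(rbinom(1, N_per, p_std[s]), rbinom(1, N_non, p_non[s])),
      indicator = "RHF", definition = c("standard", "nonstandard"))
  })
  obs <- do.call(rbind, rows)
  class(obs) <- c("observation_set", "data.frame")
  obs
}

test_that("identity calibration recovers intercept 0 and slope 1", {
  obs <- make_pairs(60, offset = 0, slope = 1, seed = 4)
  m <- fit_definition_adjustment(obs)
  expect_lt(abs(m$intercept), 0.05)
  expect_lt(abs(m$slope - 1), 0.05)
  expect_equal(m$n_calibration, 60)
})

test_that("intercept CI covers a known logit offset in most replicates", {
  # the non-standard arm gets a large denominator so its empirical logit is
  # essentially noiseless and the binomial regression is well specified
  hits <- 0L
  for (r in 1:100) {
    obs <- make_pairs(40, offset = -0.5, slope = 1, N_per = 100L,
                      N_non = 50000L, seed = 100 + r)
    agg_k <- tapply(obs$k, list(obs$survey_id, obs$definition), sum)
    agg_N <- tapply(obs$N, list(obs$survey_id, obs$definition), sum)
    el_non <- log((agg_k[, "nonstandard"] + 0.5) /
                    (agg_N[, "nonstandard"] - agg_k[, "nonstandard"] + 0.5))
    fit <- glm(cbind(agg_k[, "standard"],
                     agg_N[, "standard"] - agg_k[, "standard"]) ~ el_non,
               family = binomial())
    ci <- suppressMessages(confint.default(fit))[1, ]
    if (ci[1] <= -0.5 && -0.5 <= ci[2]) hits <- hits + 1L
    # package fit agrees with the direct glm route
    m <- fit_definition_adjustment(obs)
    expect_equal(m$intercept, unname(coef(fit)[1]), tolerance = 1e-8)
  }
  expect_gte(hits, 90)
})

test_that("calibration requires at least two paired surveys", {
  obs <- make_pairs(1)
  expect_error(fit_definition_adjustment(obs), "calibration overlap")
})

test_that("identity adjustment leaves counts unchanged", {
  obs <- make_pairs(10, seed = 3)
  m <- structure(list(intercept = 0, slope = 1, n_calibration = 10,
                      indicator = "RHF", fallback = FALSE),
                 class = "adjustment_model")
  adj <- apply_adjustment(obs, m)
  expect_identical(adj$k, obs$k)
  expect_true(all(adj$definition %in% c("standard", "standard(adjusted)")))
})

test_that("adjustment follows closed-form logit arithmetic and bounds", {
  obs <- make_pairs(2, seed = 5)
  obs <- obs[obs$definition == "nonstandard", ][1, ]
  obs$N <- 10L; obs$k <- 5L
  class(obs) <- c("observation_set", "data.frame")
  m <- structure(list(intercept = -0.5, slope = 1, n_calibration = 2,
                      indicator = "RHF", fallback = FALSE),
                 class = "adjustment_model")
  adj <- apply_adjustment(obs, m)
  expect_equal(plogis(-0.5), 0.3775, tolerance = 5e-4)
  expect_equal(adj$k, 4)

  obs$k <- 0L
  adj0 <- apply_adjustment(obs, m)
  expect_true(adj0$k >= 0 && adj0$k <= adj0$N)
  obs$k <- 10L
  adj1 <- apply_adjustment(obs, m)
  expect_true(adj1$k >= 0 && adj1$k <= adj1$N)
})

test_that("adjustment is monotone and invertible within rounding error", {
  m <- structure(list(intercept = 0.3, slope = 1.2, n_calibration = 5,
                      indicator = "RHF", fallback = FALSE),
                 class = "adjustment_model")
  N <- 50L
  base <- make_pairs(1, seed = 8)[2, ]
  props <- numeric(N + 1L)
  for (k in 0:N) {
    o <- base; o$N <- N; o$k <- k
    class(o) <- c("observation_set", "data.frame")
    props[k + 1L] <- apply_adjustment(o, m)$k / N
  }
  expect_true(all(diff(props) >= 0))

  # round-trip through the inverse mapping
  inv <- structure(list(intercept = -m$intercept / m$slope,
                        slope = 1 / m$slope, n_calibration = 5,
                        indicator = "RHF", fallback = FALSE),
                   class = "adjustment_model")
  for (k in c(3L, 17L, 25L, 41L)) {
    o <- base; o$N <- N; o$k <- k
    class(o) <- c("observation_set", "data.frame")
    fwd <- apply_adjustment(o, m)
    fwd$definition <- "nonstandard"
    back <- apply_adjustment(fwd, inv)
    expect_lte(abs(back$k / N - k / N), 1.5 / N)
  }
})

test_that("a non-positive slope falls back to the offset-only model", {
  # anti-monotone pairing forces a negative fitted slope
  obs <- make_pairs(30, offset = 0, slope = -1, seed = 12)
  expect_warning(m <- fit_definition_adjustment(obs), "offset-only")
  expect_equal(m$slope, 1)
  expect_true(m$fallback)
})
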