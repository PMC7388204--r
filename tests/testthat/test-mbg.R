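one_rec <- function(cell, year, N, k, geo = "point", poly = NA_integer_) {
  o <- data.frame(survey_id = "s1", year = year, geo_type = geo,
                  cell_id = if (geo == "point") cell else NA_integer_,
                  polygon_id = poly, N = N, k = k, indicator = "ORS",
                  definition = "standard")
  class(o) <- c("observation_set", "data.frame")
  o
}

test_that("log likelihood matches the binomial closed form", {
  g <- small_grid()
  p <- raster_cube(matrix(0.5, g$n_cells, length(g$years)), g, "p")
  o <- one_rec(0L, 2000L, 2L, 1L)
  expect_equal(log_likelihood(p, o), dbinom(1, 2, 0.5, log = TRUE))
  expect_equal(dbinom(1, 2, 0.5, log = TRUE), log(0.5), tolerance = 1e-12)
})

test_that("log likelihood equals a term-by-term brute-force sum", {
  set.seed(31)
  g <- small_grid()
  pm <- matrix(runif(g$n_cells * length(g$years), 0.05, 0.95), g$n_cells)
  p <- raster_cube(pm, g, "p")
  n <- 50
  cells <- sample(0:(g$n_cells - 1), n, replace = TRUE)
  years <- sample(g$years, n, replace = TRUE)
  N <- 1L + rpois(n, 6)
  pr <- pm[cbind(cells + 1, match(years, g$years))]
  k <- rbinom(n, N, pr)
  o <- data.frame(survey_id = "s", year = years, geo_type = "point",
                  cell_id = cells, polygon_id = NA_integer_, N = N, k = k,
                  indicator = "ORS", definition = "standard")
  class(o) <- c("observation_set", "data.frame")
  brute <- sum(sapply(seq_len(n), function(i)
    dbinom(k[i], N[i], pr[i], log = TRUE)))
  expect_equal(log_likelihood(p, o), brute, tolerance = 1e-12)
})

test_that("polygon likelihood uses the population-weighted probability", {
  g <- grid_spec(2, 2, years = 2000L, n_countries = 1,
                 admin1_per_country = 1, admin2_per_admin1 = 2,
                 n_regions = 1)
  pm <- matrix(c(0.2, 0.4, 0.2, 0.4), 4, 1)
  p <- raster_cube(pm, g, "p")
  pop <- raster_cube(matrix(100, 4, 1), g, "pop")
  o <- one_rec(NA, 2000L, 10L, 3L, geo = "polygon", poly = 0L)
  expect_equal(log_likelihood(p, o, pop = pop),
               dbinom(3, 10, 0.3, log = TRUE))
  expect_error(log_likelihood(p, one_rec(99L, 2000L, 2L, 1L)), "missing cell")
})

test_that("empty observation sets and degenerate draw counts error", {
  g <- small_grid()
  expect_error(mbg(NULL, g), "empty")
  w <- test_world()
  obs <- w$observations$ORS[w$observations$ORS$geo_type == "point", ][1:40, ]
  fit <- mbg(obs, g,
             spec = mbg_spec(fix_theta = c(sigma2_sp = 0.3, range_sp = 5,
                                           rho_t = 0.5,
                                           tau2_nugget = 0.05)))
  expect_error(draw_posterior_surfaces(fit, n_draws = 1), ">= 2")
})

test_that("posterior surface draws are seeded, joint and in (0,1)", {
  g <- small_grid()
  w <- test_world()
  obs <- w$observations$ORS[w$observations$ORS$geo_type == "point", ]
  fit <- mbg(obs, g,
             spec = mbg_spec(optim_maxit = 30, n_hyper = 4), seed = 3)
  a <- draw_posterior_surfaces(fit, n_draws = 20, seed = 5)
  b <- draw_posterior_surfaces(fit, n_draws = 20, seed = 5)
  expect_identical(a$p, b$p)
  expect_equal(dim(a$p), c(g$n_cells, length(g$years), 20L))
  expect_true(all(a$p > 0 & a$p < 1))
  expect_false(anyNA(a$p))
})

test_that("a flat-truth intercept-only fit recovers the intercept", {
  g <- small_grid()
  set.seed(41)
  n <- 2000
  cells <- sample(0:(g$n_cells - 1), n, replace = TRUE)
  o <- data.frame(survey_id = "s", year = 2000L, geo_type = "point",
                  cell_id = cells, polygon_id = NA_integer_, N = 1L,
                  k = rbinom(n, 1, 0.3), indicator = "ORS",
                  definition = "standard")
  class(o) <- c("observation_set", "data.frame")
  fit <- mbg(o, g,
             spec = mbg_spec(fix_theta = c(sigma2_sp = 1e-6, range_sp = 5,
                                           rho_t = 0.5,
                                           tau2_nugget = 1e-6),
                             n_hyper = 2), seed = 6)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - qlogis(0.3)), 0.15)
})

test_that("fits are deterministic given seed and independent of other data", {
  g <- small_grid()
  w <- test_world()
  obs <- w$observations$ORS
  reg2_admin1 <- unique(g$membership$admin1_id[g$membership$region_id == 1])
  in2 <- (obs$geo_type == "point" &
            obs$cell_id %in% g$membership$cell_id[g$membership$region_id == 1]) |
    (obs$geo_type == "polygon" & obs$polygon_id %in% reg2_admin1)
  o2 <- obs[in2, ]
  spec <- mbg_spec(optim_maxit = 25, n_hyper = 3)
  f1 <- mbg(o2, g, pop = w$population, spec = spec, seed = 4)
  f2 <- mbg(o2, g, pop = w$population, spec = spec, seed = 4)
  expect_identical(f1$theta_mode, f2$theta_mode)
  expect_identical(f1$mode_state$g, f2$mode_state$g)
  d1 <- draw_posterior_surfaces(f1, 10, seed = 2)
  d2 <- draw_posterior_surfaces(f2, 10, seed = 2)
  expect_identical(d1$p, d2$p)
})

test_that("the MCMC backend agrees with the Laplace fit on a small case", {
  g <- grid_spec(8, 8, years = 2000:2001, n_countries = 2,
                 admin1_per_country = 2, admin2_per_admin1 = 2,
                 n_regions = 1)
  truth <- simulate_truth(g, NULL,
                          truth_params(alpha = -0.4, sigma2_sp = 0.3,
                                       range_sp = 4, rho_t = 0.6,
                                       tau2_nugget = 0.02, trend = 0),
                          "ORS", seed = 2)
  pop <- simulate_population(g, seed = 3)
  obs <- point_obs(truth, pop, n_surveys = 4, clusters = 40, seed = 4)
  fl <- mbg(obs, g, spec = mbg_spec(optim_maxit = 40, n_hyper = 4), seed = 5)
  fm <- mbg(obs, g, spec = mbg_spec(method = "mcmc",
                                    mcmc = list(n_iter = 800, burnin = 300,
                                                thin = 5)), seed = 5)
  expect_lt(abs(coef(fl)[["(Intercept)"]] - coef(fm)[["(Intercept)"]]), 0.3)
  cube <- draw_posterior_surfaces(fm, n_draws = 10, seed = 1)
  expect_true(all(cube$p > 0 & cube$p < 1))
})

test_that("fit methods expose fitted values, residuals and draws coherently", {
  g <- small_grid()
  w <- test_world()
  obs <- w$observations$ORS[w$observations$ORS$geo_type == "point", ]
  fit <- mbg(obs, g, spec = mbg_spec(optim_maxit = 25, n_hyper = 3),
             seed = 9)
  expect_equal(length(fitted(fit)), nrow(obs))
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  expect_equal(residuals(fit), obs$k / obs$N - fitted(fit))
  s <- summary(fit)
  expect_true(all(s$hyper$lower95 <= s$hyper$mean &
                    s$hyper$mean <= s$hyper$upper95))
  cube <- simulate(fit, nsim = 5, seed = 1)
  expect_s3_class(cube, "draw_cube")
  pm <- predict(fit, n_draws = 5, seed = 1)
  expect_equal(dim(pm), c(g$n_cells, length(g$years)))
})
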