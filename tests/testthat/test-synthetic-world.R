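test_that("covariate simulation is seeded and flags collinearity", {
  g <- small_grid()
  a <- simulate_covariates(g, n_layers = 8, collinear_pairs = 1, seed = 7)
  b <- simulate_covariates(g, n_layers = 8, collinear_pairs = 1, seed = 7)
  expect_identical(a$values, b$values)

  # each layer standardized over cells
  for (j in 1:8) {
    x <- a$values[, 1, j]
    expect_equal(mean(x), 0, tolerance = 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
  # the engineered layer has squared multiple correlation > 0.9
  X <- a$values[, 1, ]
  r2 <- sapply(1:8, function(j) {
    f <- lm.fit(cbind(1, X[, -j]), X[, j])
    1 - sum(f$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
  })
  expect_gt(max(r2), 0.9)

  expect_error(simulate_covariates(g, n_layers = 1, collinear_pairs = 1),
               "at least 2")
  expect_error(simulate_covariates(g, n_layers = 3, collinear_pairs = 3),
               "smaller")
})

test_that("truth surface honours the identity and monotonicity cases", {
  g <- small_grid()
  p0 <- truth_params(alpha = 0, sigma2_sp = 0, tau2_nugget = 0, trend = 0)
  tr <- simulate_truth(g, NULL, p0, "ORS", seed = 1)
  expect_true(all(cube_layer(tr, "p") == 0.5))

  pt <- truth_params(alpha = 0, sigma2_sp = 0, tau2_nugget = 0, trend = 0.3)
  tr2 <- cube_layer(simulate_truth(g, NULL, pt, "ORS", seed = 1), "p")
  expect_true(all(apply(tr2, 1, diff) > 0))

  expect_error(
    simulate_truth(g, simulate_covariates(g, 4, 0, seed = 1),
                   truth_params(beta = c(1, 2)), "ORS", seed = 1),
    "match")
})

test_that("logit-truth variogram rises with distance up to the range", {
  g <- grid_spec(15, 15, years = 2000L, n_countries = 3,
                 admin1_per_country = 2, admin2_per_admin1 = 2, n_regions = 1)
  pars <- truth_params(alpha = 0, sigma2_sp = 1, range_sp = 6, rho_t = 0.5,
                       tau2_nugget = 0, trend = 0)
  # Monte Carlo semivariance of logit p at lags 1, 3, 5 over replicates;
  # oracle: gamma(h) = sigma2 * (1 - matern32(h, range)), increasing in h
  lags <- c(1, 3, 5)
  acc <- matrix(0, 100, length(lags))
  D <- as.matrix(dist(g$coords))
  idx <- lapply(lags, function(h) which(abs(D - h) < 1e-9, arr.ind = TRUE))
  for (r in 1:100) {
    z <- qlogis(cube_layer(simulate_truth(g, NULL, pars, "ORS", seed = r),
                           "p"))
    for (l in seq_along(lags)) {
      ij <- idx[[l]]
      acc[r, l] <- mean((z[ij[, 1]] - z[ij[, 2]])^2) / 2
    }
  }
  gam <- colMeans(acc)
  expect_true(all(diff(gam) > 0))
  oracle <- 1 * (1 - matern32(lags, 6))
  expect_equal(gam, oracle, tolerance = 0.15)
})

test_that("surveys respect the binomial contract at scale", {
  g <- small_grid()
  w <- test_world()
  obs <- simulate_surveys(w$truth$ORS, w$population,
                          list(n_surveys = 40, clusters_per_survey = 2500,
                               mean_N = 5), seed = 9)
  expect_gte(nrow(obs), 1e5)
  expect_true(all(obs$N >= 1))
  expect_true(all(obs$k >= 0 & obs$k <= obs$N))
})

test_that("boundary truth gives fully treated records", {
  g <- small_grid()
  p1 <- truth_params(alpha = 40, sigma2_sp = 0, tau2_nugget = 0)
  tr <- simulate_truth(g, NULL, p1, "ORS", seed = 1)
  pop <- simulate_population(g, seed = 2)
  obs <- point_obs(tr, pop)
  expect_true(all(obs$k == obs$N))
})

test_that("zero definition offset leaves definitions exchangeable", {
  w <- test_world()
  obs <- simulate_surveys(w$truth$RHF, w$population,
                          list(n_surveys = 30, clusters_per_survey = 60,
                               nonstandard_fraction = 0.5, defn_offset = 0,
                               both_fraction = 0),
                          seed = 21)
  a <- obs[obs$definition == "standard", ]
  b <- obs[obs$definition == "nonstandard", ]
  pt <- prop.test(c(sum(a$k), sum(b$k)), c(sum(a$N), sum(b$N)))
  expect_gt(pt$p.value, 0.01)
})

test_that("pooled survey estimate matches population-weighted truth", {
  w <- test_world()
  truth <- w$truth$ORS
  # nugget-free copy so the binomial SE oracle is exact
  attr(truth, "tau2_nugget") <- 0
  obs <- simulate_surveys(truth, w$population,
                          list(n_surveys = 4, clusters_per_survey = 200,
                               mean_N = 10, polygon_fraction = 0), seed = 5)
  p_mat <- cube_layer(truth, "p")
  pop1 <- cube_layer(w$population, 1)[, 1]
  for (yr in unique(obs$year)) {
    o <- obs[obs$year == yr, ]
    t <- match(yr, truth$grid$years)
    target <- weighted.mean(p_mat[, t], pop1)
    est <- sum(o$k) / sum(o$N)
    se <- sqrt(est * (1 - est) / sum(o$N))
    # 3 MC standard errors, plus allowance for finite-cluster sampling
    expect_lt(abs(est - target), 3 * se + 0.05)
  }
})

test_that("mortality link follows its closed form and degenerate cases", {
  g <- small_grid()
  ones <- raster_cube(matrix(0.75, g$n_cells, length(g$years)), g, "p")
  pop <- raster_cube(matrix(1000, g$n_cells, length(g$years)), g, "pop")
  m <- simulate_mortality(ones, pop, list(base_rate = 0.01, epsilon = 0.92))
  expect_equal(unique(as.numeric(cube_layer(m, 1))),
               1000 * 0.01 * (1 - 0.92 * 0.75))
  expect_equal(1 - 0.92 * 0.75, 0.31)

  w <- test_world()
  m0 <- simulate_mortality(w$truth$ORS, w$population,
                           list(epsilon = 0))
  rate0 <- cube_layer(m0, 1)[, 1] / cube_layer(w$population, 1)[, 1]
  expect_lt(sd(rate0), 1e-12)  # rate independent of coverage

  m1 <- simulate_mortality(w$truth$ORS, w$population,
                           list(epsilon = 0.6, noise_sd = 0))
  p <- cube_layer(w$truth$ORS, "p")
  d <- cube_layer(m1, 1)
  varying <- which(apply(p, 1, sd) > 1e-8)
  cors <- sapply(varying, function(i) cor(p[i, ], d[i, ]))
  expect_true(all(abs(cors + 1) < 1e-8))

  expect_error(simulate_mortality(ones, pop, list(epsilon = 1)), "epsilon")
  expect_error(simulate_mortality(ones, pop, list(base_rate = 0)),
               "base_rate")
})

test_that("simulated worlds keep ORT coverage above ORS coverage", {
  w <- test_world()
  expect_true(all(cube_layer(w$truth$ORT, "p") >=
                    cube_layer(w$truth$ORS, "p")))
  expect_true(all(cube_layer(w$truth$ORT, "p") >=
                    cube_layer(w$truth$RHF, "p")))
})
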