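# hand-built draw cube helper
toy_cube <- function(grid, p_array) {
  structure(list(p = p_array, grid = grid, n_draws = dim(p_array)[3]),
            class = "draw_cube")
}

test_that("uncertainty summaries follow the documented percentile rule", {
  expect_equal(summarize_ui(rep(0.3, 250)),
               c(mean = 0.3, lower95 = 0.3, upper95 = 0.3))
  s <- summarize_ui((1:100) / 100)
  # type-7 linear interpolation: rank 1 + 99 p, symmetric around 50.5
  expect_equal(s[["lower95"]], 0.03475, tolerance = 1e-10)
  expect_equal(s[["upper95"]], 0.97525, tolerance = 1e-10)
  set.seed(1)
  x <- runif(100)
  expect_equal(summarize_ui(x)[["mean"]], summarize_ui(rev(x))[["mean"]])
  expect_error(summarize_ui(0.5), "at least 2")
  expect_error(summarize_ui(c(0.1, NaN)), "NaN")
})

test_that("aggregation is exact for constants and weighted means", {
  g <- small_grid()
  pop <- simulate_population(g, seed = 1)
  cube <- toy_cube(g, array(0.42, c(g$n_cells, length(g$years), 5)))
  agg <- aggregate_draws(cube, pop, "admin2")
  expect_true(all(abs(agg$draws - 0.42) < 1e-12))

  # two-cell weighted mean oracle
  g2 <- grid_spec(2, 2, years = 2000L, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  n_regions = 1)
  pop2 <- raster_cube(matrix(c(100, 300, 0, 0), 4, 1), g2, "pop")
  p2 <- array(c(0.2, 0.4, 0.9, 0.9), c(4, 1, 2))
  p2[, , 2] <- p2[, , 1]
  agg2 <- aggregate_draws(toy_cube(g2, p2), pop2, "country")
  expect_equal(unname(agg2$draws[1, 1, 1]), 0.35)
})

test_that("country aggregates equal pop-weighted means of admin1 values", {
  g <- small_grid()
  pop <- simulate_population(g, seed = 2)
  set.seed(3)
  p <- array(runif(g$n_cells * length(g$years) * 4),
             c(g$n_cells, length(g$years), 4))
  cube <- toy_cube(g, p)
  a1 <- aggregate_draws(cube, pop, "admin1")
  co <- aggregate_draws(cube, pop, "country")
  map <- unique(g$membership[, c("admin1_id", "country_id")])
  for (cn in co$units) {
    ids <- map$admin1_id[map$country_id == cn]
    i <- match(ids, a1$units)
    w <- a1$pop_totals[i, 1]
    expect_equal(co$draws[match(cn, co$units), 1, 1],
                 weighted.mean(a1$draws[i, 1, 1], w), tolerance = 1e-12)
  }
})

test_that("aggregation matches a brute-force weighted mean on random data", {
  g <- small_grid()
  set.seed(4)
  popm <- matrix(rexp(g$n_cells * length(g$years)), g$n_cells)
  pop <- raster_cube(popm, g, "pop")
  p <- array(runif(g$n_cells * length(g$years) * 3),
             c(g$n_cells, length(g$years), 3))
  agg <- aggregate_draws(toy_cube(g, p), pop, "admin2")
  mem <- g$membership
  for (trial in 1:10) {
    u <- sample(agg$units, 1); t <- sample(seq_along(g$years), 1)
    d <- sample(3, 1)
    cells <- mem$cell_id[mem$admin2_id == u] + 1
    expect_equal(agg$draws[match(u, agg$units), t, d],
                 weighted.mean(p[cells, t, d], popm[cells, t]),
                 tolerance = 1e-12)
  }
})

test_that("AROC follows per-draw logit arithmetic with a significance flag", {
  # no change: mean zero, not significant
  g2 <- grid_spec(2, 2, years = c(2000L, 2017L), n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  n_regions = 1)
  pop <- raster_cube(matrix(1, 4, 2), g2, "pop")
  p <- array(0.4, c(4, 2, 10))
  agg <- aggregate_draws(toy_cube(g2, p), pop, "country")
  ar <- compute_aroc(agg, 2000, 2017)
  expect_equal(ar$mean, 0)
  expect_false(ar$significant)

  # single-draw oracle: 0.12 -> 0.339 over 17 years = 7.79% per year
  p2 <- array(NA_real_, c(4, 2, 2))
  p2[, 1, ] <- 0.12; p2[, 2, ] <- 0.339
  agg2 <- aggregate_draws(toy_cube(g2, p2), pop, "country")
  ar2 <- compute_aroc(agg2, 2000, 2017)
  expect_equal(ar2$mean, 100 * (qlogis(0.339) - qlogis(0.12)) / 17,
               tolerance = 1e-10)
  expect_equal(round(ar2$mean, 2), 7.79)
  expect_true(ar2$significant)  # all draws positive

  # clipping warning at the boundary
  p3 <- array(c(rep(1, 8), rep(0.5, 8)), c(4, 2, 2))
  agg3 <- aggregate_draws(toy_cube(g2, p3), pop, "country")
  expect_warning(compute_aroc(agg3, 2000, 2017), "clipped")
})

test_that("untreated counts obey full coverage, arithmetic and additivity", {
  g <- small_grid()
  nyr <- length(g$years)
  ep <- raster_cube(matrix(100, g$n_cells, nyr), g, "episodes")
  full <- toy_cube(g, array(1, c(g$n_cells, nyr, 3)))
  u <- count_untreated(full, ep, "admin2", g$years[1])
  expect_equal(u$total[["mean"]], 0)

  p <- toy_cube(g, array(0.4, c(g$n_cells, nyr, 3)))
  u2 <- count_untreated(p, ep, "country", g$years[1])
  expect_equal(u2$total[["mean"]], g$n_cells * 100 * 0.6)
  # one cell with 100 episodes at p = 0.4 contributes 60 untreated
  expect_equal(u2$per_unit$mean / (g$n_cells / 3), rep(60, 3))

  set.seed(5)
  pr <- toy_cube(g, array(runif(g$n_cells * nyr * 4), c(g$n_cells, nyr, 4)))
  ua <- count_untreated(pr, ep, "admin2", g$years[2])
  uc <- count_untreated(pr, ep, "country", g$years[2])
  expect_equal(colSums(ua$draws), colSums(uc$draws), tolerance = 1e-9)
  expect_error(count_untreated(pr, ep, "admin2", 1990), "not in cube")
})

test_that("proportion below threshold reproduces printed-count arithmetic", {
  sm <- data.frame(unit_id = 1:1000, level = "admin2", year = 2017,
                   mean = c(rep(0.3, 626), rep(0.7, 374)),
                   lower95 = 0, upper95 = 1)
  pb <- proportion_below(sm, 0.5)
  expect_equal(pb$count, 626)
  expect_equal(pb$pct, 62.6)
  sm$mean <- 0.9
  expect_equal(proportion_below(sm, 0.5)$pct, 0)
  expect_equal(proportion_below(sm, 1.0)$pct, 100)
})

test_that("trend correlations match the Pearson formula and edge cases", {
  yrs <- as.character(2000:2003)
  A <- matrix(c(1, 2, 3, 4,  1, 1, 1, 1,  0.3, 0.1, 0.4, 0.2), 3, 4,
              byrow = TRUE, dimnames = list(c("u1", "u2", "u3"), yrs))
  B <- matrix(c(4, 3, 2, 1,  2, 2, 2, 2,  0.2, 0.5, 0.1, 0.3), 3, 4,
              byrow = TRUE, dimnames = list(c("u1", "u2", "u3"), yrs))
  ct <- correlate_trends(A, B)
  expect_equal(ct$per_unit$r[1], -1)
  expect_true(is.na(ct$per_unit$r[2]))  # zero-variance unit excluded
  a <- A["u3", ]; b <- B["u3", ]
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ct$per_unit$r[3], unname(brute), tolerance = 1e-12)
  expect_equal(ct$n_assessed, 2)
  expect_equal(correlate_trends(A, A)$per_unit$r[1], 1)
})
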