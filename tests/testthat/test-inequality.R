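brute_gini <- function(x, w) {
  w <- w / sum(w)
  acc <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    acc <- acc + w[i] * w[j] * abs(x[i] - x[j])
  acc / (2 * sum(w * x))
}

test_that("gini honours the worked examples", {
  expect_equal(gini(rep(0.3, 10), runif(10, 1, 5)), 0)
  expect_equal(gini(c(0, 1), c(1, 1)), 0.5)
  expect_equal(gini(c(1, 0), c(0.9, 0.1)), 0.1)
  expect_error(gini(c(0, 0)), "undefined")
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("gini matches the brute-force pairwise oracle and its bounds", {
  set.seed(11)
  for (r in 1:40) {
    n <- sample(2:50, 1)
    x <- runif(n)
    w <- rexp(n) + 0.01
    g <- gini(x, w)
    expect_equal(g, brute_gini(x, w), tolerance = 1e-12)
    expect_lte(g, 1 - min(w / sum(w)) + 1e-12)
    # scale invariance
    expect_equal(gini(3.7 * x, w), g, tolerance = 1e-12)
    # equal weights reduce to the unweighted formula
    expect_equal(gini(x), brute_gini(x, rep(1, n)), tolerance = 1e-12)
  }
})

test_that("deviations from the country mean follow their definitions", {
  d <- deviation_from_mean(c(a = 0.3, b = 0.45), 0.30)
  expect_equal(d$abs_dev_pp, c(0, 15))
  expect_equal(d$rel_dev_pct, c(0, 50))
  expect_warning(deviation_from_mean(c(a = 0.1), 0), "undefined")

  # population-weighted deviations sum to zero around the weighted mean
  set.seed(12)
  p <- runif(8); w <- rexp(8)
  cm <- weighted.mean(p, w)
  dd <- deviation_from_mean(p, cm)
  expect_equal(sum(w * dd$abs_dev_pp), 0, tolerance = 1e-9)

  # unit invariance of relative deviation (probabilities vs percentages)
  d1 <- deviation_from_mean(p, cm)
  d2 <- deviation_from_mean(100 * p, 100 * cm)
  expect_equal(d1$rel_dev_pct, d2$rel_dev_pct, tolerance = 1e-10)
})

test_that("inequality records and trends flag the documented patterns", {
  g <- small_grid()
  pop <- simulate_population(g, seed = 13)
  nyr <- length(g$years)
  set.seed(14)
  p <- array(runif(g$n_cells * nyr * 4, 0.2, 0.8), c(g$n_cells, nyr, 4))
  cube <- structure(list(p = p, grid = g, n_draws = 4), class = "draw_cube")
  agg <- aggregate_draws(cube, pop, "admin2")
  r0 <- inequality_record(agg, g$membership, g$years[1])
  r1 <- inequality_record(agg, g$membership, g$years[nyr])
  expect_true(all(r0$gini$gini >= 0 & r0$gini$gini <= 1))
  # weighted deviations sum to zero within each country
  for (cn in unique(r0$deviations$country_id)) {
    d <- r0$deviations[r0$deviations$country_id == cn, ]
    w <- agg$pop_totals[match(d$unit_id, agg$units), 1]
    expect_equal(sum(w * d$abs_dev_pp) / sum(w), 0, tolerance = 1e-9)
  }

  tr_same <- inequality_trends(r0, r0)
  expect_false(any(tr_same$per_country$gini_declined))
  expect_false(any(tr_same$per_country$abs_range_declined))

  # 63 decliners of 94 countries reports as 67%
  mk <- function(gv) {
    structure(list(
      gini = data.frame(country_id = 1:94, year = 2000, gini = gv),
      deviations = data.frame(country_id = rep(1:94, each = 2),
                              unit_id = 1:188, year = 2000,
                              abs_dev_pp = 0, rel_dev_pct = 0),
      year = 2000), class = "inequality_record")
  }
  t63 <- inequality_trends(mk(rep(0.2, 94)),
                           mk(c(rep(0.1, 63), rep(0.3, 31))))
  expect_equal(t63$counts$gini_declined, 63)
  expect_equal(t63$counts$gini_declined_pct, 67)
  t54 <- inequality_trends(mk(rep(0.2, 94)),
                           mk(c(rep(0.1, 54), rep(0.3, 40))))
  expect_equal(t54$counts$gini_declined_pct, 57)

  # a unit at 1.6x the country mean triggers the >= 50% relative flag
  g1 <- grid_spec(4, 4, years = 2000L, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 4,
                  n_regions = 1)
  popc <- raster_cube(matrix(1, 16, 1), g1, "pop")
  pv <- rep(0.3, 16)
  hot <- g1$membership$cell_id[g1$membership$admin2_id == 0] + 1
  pv[hot] <- 0.6  # unit sits at exactly 1.6x the resulting country mean
  pc <- array(rep(pv, 2), c(16, 1, 2))
  aggc <- aggregate_draws(structure(list(p = pc, grid = g1, n_draws = 2),
                                    class = "draw_cube"), popc, "admin2")
  rc <- inequality_record(aggc, g1$membership, 2000)
  expect_true(any(abs(rc$deviations$rel_dev_pct) >= 50))

  expect_error(inequality_trends(mk(rep(0.2, 94)),
                                 structure(list(gini = data.frame(
                                   country_id = 1:90, year = 2017,
                                   gini = 0.1)), class = "inequality_record")),
               "mismatched")
})
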