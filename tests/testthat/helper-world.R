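# Shared small-world fixtures, built once per test session.

small_grid <- function(years = 2000:2003) {
  grid_spec(12, 12, years = years, n_countries = 3L,
            admin1_per_country = 2L, admin2_per_admin1 = 2L, n_regions = 2L)
}

# memoised desk-scale world used by several test files
.world_cache <- new.env(parent = emptyenv())
test_world <- function() {
  if (is.null(.world_cache$w)) {
    .world_cache$w <- simulate_world(
      small_grid(), survey_design = list(n_surveys = 8L,
                                         clusters_per_survey = 30L),
      seed = 11L)
  }
  .world_cache$w
}

# quick point-only observation set on a given truth
point_obs <- function(truth, pop, n_surveys = 8L, clusters = 40L, seed = 2L) {
  simulate_surveys(truth, pop,
                   list(n_surveys = n_surveys, clusters_per_survey = clusters,
                        polygon_fraction = 0), seed = seed)
}
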