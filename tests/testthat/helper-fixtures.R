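# Small-population truth for fast unit tests: same coefficients and noise
# as the default study, fewer trees per group.
small_truth <- function(n = 6L, seed = 1L, ...) {
  synthetic_truth(n_trees = c(spruce_PBS = n, spruce_M = n, spruce_PTA = n,
                              aspen_PTA = n, aspen_M = n),
                  seed = seed, ...)
}

# One shared small synthetic study, built once per test run.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(small_truth())
    cache
  }
})

# Constant-covariate table for exercising the model without climate noise.
flat_covariates <- function(years = 1950:2005) {
  data.frame(year = years,
             trend = as.integer(build_trend_covariate(years)),
             season_length = 0, summer_heat = 0,
             sbw = as.numeric(build_sbw_covariate(years = years)),
             ftc = as.numeric(build_ftc_covariate(years = years)))
}

# Deterministic non-degenerate covariates (no RNG) for sampler tests.
sim_covariates <- function(years = 1950:2005) {
  t <- seq_along(years)
  data.frame(year = years,
             trend = as.integer(build_trend_covariate(years)),
             season_length = sin(t / 3) * 1.2,
             summer_heat = cos(t / 5) * 0.9,
             sbw = as.numeric(build_sbw_covariate(years = years)),
             ftc = as.numeric(build_ftc_covariate(years = years)))
}

make_series <- function(widths, id = "T1", first_year = 1950, ...) {
  ring_width_series(tree_id = id, species = "black_spruce",
                    stand_type = "PBS", first_year = first_year,
                    widths = widths, ...)
}
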