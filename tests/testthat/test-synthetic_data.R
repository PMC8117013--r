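test_that("monthly climate generator honors climatology, ordering and seeds", {
  years <- 1950:1959
  p0 <- climate_gen_params(tavg_sd = rep(1e-12, 12), prcp_cv = 0)
  clim0 <- generate_monthly_climate(p0, years, seed = 3)
  julys <- clim0$tavg_c[clim0$month == 7]
  expect_equal(julys, rep(16.9, length(years)), tolerance = 1e-9)
  expect_true(all(clim0$tmin_c <= clim0$tavg_c &
                  clim0$tavg_c <= clim0$tmax_c))
  expect_true(all(clim0$prcp_mm >= 0))

  a <- generate_monthly_climate(years = 1950:1970, seed = 5)
  b <- generate_monthly_climate(years = 1950:1970, seed = 5)
  expect_identical(a, b)
  c2 <- generate_monthly_climate(years = 1950:1970, seed = 6)
  expect_false(identical(a$tavg_c, c2$tavg_c))

  expect_error(generate_monthly_climate(years = integer(0)), "nonempty")
  expect_error(climate_gen_params(tavg_sd = c(rep(1, 11), -1)), "sd")
})

test_that("simulated July means match the generating climatology", {
  # Monte-Carlo oracle: mean of N simulated Julys ~ N(16.9, sd/sqrt(N))
  clim <- generate_monthly_climate(years = 1:10000, seed = 17)
  julys <- clim$tavg_c[clim$month == 7]
  se <- climate_gen_params()$tavg_sd[7] / sqrt(length(julys))
  expect_lt(abs(mean(julys) - 16.9), 3 * se)
})

test_that("group BAI equals the linear predictor plus AR(1) noise", {
  cov <- flat_covariates()
  base_only <- synthetic_truth(
    group_params = list(g = list(alpha = c(baseline = 3, trend = 0,
                                           season_length = 0,
                                           summer_heat = 0, sbw = 0,
                                           ftc = 0), sigma = 0)),
    n_trees = c(g = 2L), years = 1950:2005)
  gb <- simulate_group_bai(base_only, cov, "g")
  expect_equal(gb$bai_cm2, rep(3, 56))

  sbw_only <- synthetic_truth(
    group_params = list(g = list(alpha = c(baseline = 3, trend = 0,
                                           season_length = 0,
                                           summer_heat = 0, sbw = -1,
                                           ftc = 0), sigma = 0)),
    n_trees = c(g = 2L), years = 1950:2005)
  gb2 <- simulate_group_bai(sbw_only, cov, "g")
  expect_equal(gb2$bai_cm2[gb2$year == 1974], 3 - 1)
  expect_equal(gb2$bai_cm2[gb2$year == 1965], 3)

  expect_error(simulate_group_bai(base_only, cov, "nope"), "unknown group")
  expect_error(simulate_group_bai(base_only, cov[1:10, ], "g"), "cover")
})

test_that("AR(1) noise paths reproduce the generating autocorrelation", {
  phi <- 0.7
  tr <- synthetic_truth(
    group_params = list(g = list(alpha = c(baseline = 5, trend = 0,
                                           season_length = 0,
                                           summer_heat = 0, sbw = 0,
                                           ftc = 0), sigma = 0.5)),
    ar1_coef = phi, n_trees = c(g = 2L), years = 1950:2005)
  cov <- flat_covariates()
  cov$sbw <- 0; cov$ftc <- 0
  set.seed(99)
  n_rep <- 500
  r1 <- vapply(seq_len(n_rep), function(k) {
    e <- simulate_group_bai(tr, cov, "g")$bai_cm2 - 5
    cor(e[-1], e[-length(e)])
  }, 1.0)
  # sample lag-1 autocorrelation at n=56: se ~ sqrt((1-phi^2)/n) per path,
  # biased low by ~(1+3phi)/n; allow 3 se of the replicate mean around that
  expected <- phi - (1 + 3 * phi) / 56
  se <- sd(r1) / sqrt(n_rep)
  expect_lt(abs(mean(r1) - expected), 3 * se + 0.02)
})

test_that("tree ring widths invert cumulative-area growth", {
  years <- 1950:2005
  gb <- data.frame(year = years, bai_cm2 = rep(2, length(years)))
  tr <- synthetic_truth(n_trees = c(spruce_PBS = 2L), tree_sd = 0,
                        years = years,
                        group_params = list(spruce_PBS = list(
                          alpha = c(baseline = 2, trend = 0,
                                    season_length = 0, summer_heat = 0,
                                    sbw = 0, ftc = 0), sigma = 0)))
  sim <- simulate_tree_ring_widths(tr, gb, "spruce_PBS", seed = 4)
  for (i in seq_along(sim$series)) {
    s <- sim$series[[i]]
    off <- sim$truth$pith_offset_mm[i]
    sel <- years >= sim$truth$start_year[i]
    bai <- ring_widths_to_bai(s, pith_offset = off)
    expect_equal(bai$bai_cm2, gb$bai_cm2[sel], tolerance = 1e-9)
    # constant BAI: equal area rings get thinner outward
    expect_true(all(diff(s$widths) < 0))
  }
  expect_error(simulate_tree_ring_widths(
    tr, data.frame(year = years, bai_cm2 = c(-1, rep(2, 55))),
    "spruce_PBS"), "positive")
})

test_that("averaging many trees recovers the group BAI within SEM", {
  years <- 1950:2005
  tr <- synthetic_truth(n_trees = c(spruce_M = 30L), tree_sd = 0.2,
                        years = years,
                        group_params = list(spruce_M = list(
                          alpha = c(baseline = 3, trend = 0,
                                    season_length = 0, summer_heat = 0,
                                    sbw = 0, ftc = 0), sigma = 0)))
  gb <- data.frame(year = years, bai_cm2 = seq(2, 4, length.out = 56))
  sim <- simulate_tree_ring_widths(tr, gb, "spruce_M", seed = 21)
  # recompute BAI per tree with true offsets, average on fully-covered years
  bai_list <- lapply(seq_along(sim$series), function(i)
    ring_widths_to_bai(sim$series[[i]],
                       pith_offset = sim$truth$pith_offset_mm[i]))
  late <- years[years >= max(sim$truth$start_year)]
  mat <- vapply(bai_list, function(b)
    b$bai_cm2[match(late, b$year)], numeric(length(late)))
  m <- rowMeans(mat)
  sem <- apply(mat, 1, sd) / sqrt(ncol(mat))
  truth_late <- gb$bai_cm2[match(late, gb$year)]
  expect_true(mean(abs(m - truth_late) <= 3 * sem) > 0.95)
})

test_that("default synthetic populations look like boreal ring-width data", {
  st <- small_study()
  for (g in chronology_groups()) {
    stats <- chronology_stats(st$series[[g]])
    expect_gt(stats$mean_ring_width_mm, 0.3)
    expect_lt(stats$mean_ring_width_mm, 2.5)
    expect_gt(stats$ar1, 0.3)
    expect_lt(stats$ar1, 0.95)
  }
})

test_that("the study generator is deterministic and writes a truth sidecar", {
  tr <- small_truth(n = 3L, seed = 8L)
  a <- generate_study(tr)
  b <- generate_study(tr)
  expect_identical(a$group_bai, b$group_bai)
  expect_identical(a$series$spruce_M[[1]]$widths,
                   b$series$spruce_M[[1]]$widths)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_truth_json(tr, a$tree_truth, path)
  side <- jsonlite::read_json(path)
  expect_equal(side$seed, 8L)
  expect_equal(side$group_params$spruce_M$sigma, 0.3)
  expect_equal(length(side$trees), nrow(a$tree_truth))
})
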