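test_that("distance to pith follows the circle-segment geometry", {
  s_pith <- make_series(rep(1, 6), has_pith = TRUE)
  expect_equal(estimate_distance_to_pith(s_pith), 0)

  s_arc <- make_series(rep(1, 6), arc_chord_mm = 10, arc_height_mm = 2)
  expect_equal(estimate_distance_to_pith(s_arc), 100 / 16 + 1)  # 7.25 mm

  s_fb <- make_series(c(0.5, 0.7, 0.6, 0.4, 0.8, 1))
  expect_equal(estimate_distance_to_pith(s_fb), mean(c(0.5, 0.7, 0.6,
                                                       0.4, 0.8)) * 5)
  expect_error(estimate_distance_to_pith(make_series(c(1, 1))),
               "at least 5")
})

test_that("arc-mode pith estimation recovers known synthetic offsets", {
  st <- small_study()
  errs <- c()
  for (g in chronology_groups()) {
    tt <- st$tree_truth[st$tree_truth$group == g, ]
    for (i in seq_along(st$series[[g]])) {
      s <- st$series[[g]][[i]]
      if (s$has_pith || is.na(s$arc_chord_mm)) next
      est <- estimate_distance_to_pith(s)
      errs <- c(errs, abs(est - tt$pith_offset_mm[i]))
    }
  }
  expect_gt(length(errs), 5)
  # offsets are Unif(0,10) mm (sd ~2.9); geometric estimates must beat that
  expect_lt(median(errs), sd(stats::runif(10000, 0, 10)))
  expect_lt(median(errs), 0.1)
})

test_that("BAI transform matches hand algebra and telescopes exactly", {
  b <- ring_widths_to_bai(c(1, 1), pith_offset = 0, first_year = 2000)
  expect_equal(b$bai_cm2, c(pi * 1, pi * 3) / 100, tolerance = 1e-12)

  b2 <- ring_widths_to_bai(1, pith_offset = 5, first_year = 2000)
  expect_equal(b2$bai_cm2, pi * (36 - 25) / 100, tolerance = 1e-12)

  set.seed(2)
  for (k in 1:20) {
    w <- stats::runif(sample(3:60, 1), 0.05, 3)
    off <- stats::runif(1, 0, 10)
    b3 <- ring_widths_to_bai(w, pith_offset = off, first_year = 1900)
    total <- pi * ((off + sum(w))^2 - off^2) / 100
    expect_equal(sum(b3$bai_cm2), total, tolerance = 1e-9)
  }
  expect_error(ring_widths_to_bai(c(1, -1), first_year = 1900), "widths")
})

test_that("cambial-age filter drops juvenile rings and short trees", {
  mk <- function(n, id) {
    s <- make_series(rep(1, n), id = id, first_year = 1950, has_pith = TRUE)
    list(bai = ring_widths_to_bai(s), age = cambial_ages(s))
  }
  t20 <- mk(20, "a"); t14 <- mk(14, "b")
  out <- filter_cambial_age(list(a = t20$bai, b = t14$bai),
                            list(t20$age, t14$age), min_age = 15)
  expect_equal(names(out), "a")
  expect_equal(nrow(out$a), 6L)  # 20 - 14 juvenile rings
  out1 <- filter_cambial_age(list(a = t20$bai), list(t20$age), min_age = 1)
  expect_equal(nrow(out1$a), 20L)
  # a pith-absent tree gets the configured missing-ring offset
  s_np <- make_series(rep(1, 14), id = "c")
  expect_equal(cambial_ages(s_np, missing_ring_count = 5)[1], 6L)
})

test_that("mean chronology averages trees with SEM and sample depth", {
  yrs <- 1950:1952
  b1 <- data.frame(year = yrs, bai_cm2 = c(2, 2, 2))
  b2 <- data.frame(year = yrs, bai_cm2 = c(4, 4, 4))
  ch <- build_mean_chronology(list(a = b1, b = b2), span = yrs)
  expect_equal(ch$mean_bai_cm2, rep(3, 3))
  expect_equal(ch$sem_cm2, rep(1, 3))  # sd = sqrt(2), / sqrt(2)
  expect_equal(ch$n_trees, rep(2L, 3))

  same <- build_mean_chronology(list(a = b1, b = b1), span = yrs)
  expect_equal(same$sem_cm2, rep(0, 3))
  expect_equal(same$mean_bai_cm2, b1$bai_cm2)

  # permutation invariance in tree order
  ch2 <- build_mean_chronology(list(b = b2, a = b1), span = yrs)
  expect_equal(ch2$mean_bai_cm2, ch$mean_bai_cm2)

  expect_error(build_mean_chronology(list(), span = yrs), "empty group")
  expect_error(build_mean_chronology(list(a = b1), span = 1950:1960),
               "zero trees")
})

test_that("zero-noise pipeline reproduces the generating series exactly", {
  years <- 1940:2005
  tr <- synthetic_truth(n_trees = c(spruce_PBS = 4L), tree_sd = 0,
                        years = years,
                        group_params = list(spruce_PBS = list(
                          alpha = c(baseline = 2.5, trend = 0,
                                    season_length = 0, summer_heat = 0,
                                    sbw = 0, ftc = 0), sigma = 0)))
  gb <- data.frame(year = years, bai_cm2 = rep(2.5, length(years)))
  sim <- simulate_tree_ring_widths(tr, gb, "spruce_PBS", seed = 13)
  bai_list <- lapply(seq_along(sim$series), function(i)
    ring_widths_to_bai(sim$series[[i]],
                       pith_offset = sim$truth$pith_offset_mm[i]))
  names(bai_list) <- sim$truth$tree_id
  ch <- build_mean_chronology(bai_list, span = 1960:2005)
  expect_equal(ch$mean_bai_cm2, rep(2.5, nrow(ch)), tolerance = 1e-9)
  expect_equal(max(ch$sem_cm2), 0, tolerance = 1e-9)
})

test_that("chronology recovery holds within 3 SEM across replicates", {
  years <- 1950:2005
  tmpl <- function(seed) synthetic_truth(
    n_trees = c(spruce_M = 8L), tree_sd = 0.2, years = years, seed = seed,
    group_params = list(spruce_M = list(
      alpha = c(baseline = 3, trend = 0, season_length = 0,
                summer_heat = 0, sbw = 0, ftc = 0), sigma = 0)))
  gb <- data.frame(year = years, bai_cm2 = seq(2.5, 3.5, length.out = 56))
  cover <- c()
  for (rep in 1:200) {
    sim <- simulate_tree_ring_widths(tmpl(rep), gb, "spruce_M", seed = rep)
    bai_list <- lapply(seq_along(sim$series), function(i)
      ring_widths_to_bai(sim$series[[i]],
                         pith_offset = sim$truth$pith_offset_mm[i]))
    names(bai_list) <- sim$truth$tree_id
    late <- years[years >= max(sim$truth$start_year)]
    ch <- build_mean_chronology(bai_list, span = late)
    tv <- gb$bai_cm2[match(late, gb$year)]
    cover <- c(cover, abs(ch$mean_bai_cm2 - tv) <= 3 * ch$sem_cm2)
  }
  expect_gt(mean(cover), 0.95)
})

test_that("descriptive statistics match their defining formulas", {
  s_flat <- make_series(rep(1, 4))
  s_13 <- make_series(c(1, 3, 1, 3))
  # MS of [1,3] transitions: 2|2|/4 = 1 at every step
  stats13 <- chronology_stats(list(s_13, s_13))
  expect_equal(stats13$mean_sensitivity, 1.0)
  expect_equal(stats13$series_intercorrelation, 1.0)  # self-agreement

  st <- chronology_stats(list(s_flat, s_13))
  expect_equal(st$mean_sensitivity, mean(c(0, 1)))
  # constant series has undefined AR1: excluded from the average
  expect_equal(st$ar1, cor(c(3, 1, 3), c(1, 3, 1)))

  set.seed(5)
  rnd <- lapply(1:4, function(i)
    make_series(stats::runif(30, 0.2, 2), id = paste0("r", i)))
  rs <- chronology_stats(rnd)
  expect_gte(rs$mean_sensitivity, 0); expect_lte(rs$mean_sensitivity, 2)
  expect_gte(rs$series_intercorrelation, -1)
  expect_lte(rs$series_intercorrelation, 1)
  expect_error(chronology_stats(list(s_flat)), "at least 2")
})
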