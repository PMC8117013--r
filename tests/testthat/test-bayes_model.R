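test_that("log posterior matches the closed form and an oracle summation", {
  cov <- flat_covariates()
  X <- design_matrix(cov)
  n <- nrow(X)
  alpha <- c(3, 0.01, 0.2, -0.1, -0.5, 0.6)
  y <- as.numeric(X %*% alpha)
  bounds <- default_bounds(y + rnorm(n, 0, 0.1), X)
  # perfect fit at sigma = 1: -(n/2) log(2*pi) - log(1)
  lp <- log_posterior(c(alpha, 1), y, cov, bounds)
  expect_equal(lp, -(n / 2) * log(2 * pi), tolerance = 1e-12)

  out <- bounds["upper", 1] + 1
  expect_identical(log_posterior(c(out, alpha[-1], 1), y, cov, bounds),
                   -Inf)

  # oracle: per-year normal log-pdfs summed independently, plus Jeffreys
  set.seed(44)
  for (k in 1:5) {
    th <- c(alpha + rnorm(6, 0, 0.05), runif(1, 0.2, 2))
    yk <- y + rnorm(n, 0, 0.3)
    oracle <- sum(dnorm(yk, as.numeric(X %*% th[1:6]), th[7],
                        log = TRUE)) - log(th[7])
    expect_equal(log_posterior(th, yk, cov, bounds), oracle,
                 tolerance = 1e-10)
  }
  expect_error(log_posterior(c(alpha, NA), y, cov, bounds), "non-finite")
})

test_that("near-noiseless data concentrates the posterior on the truth", {
  cov <- sim_covariates()
  X <- design_matrix(cov)
  alpha <- c(2.5, -0.02, 0.25, -0.1, -0.6, 0.8)
  set.seed(10)
  y <- as.numeric(X %*% alpha) + rnorm(nrow(X), 0, 1e-5)
  # sigma sits against its lower bound here by construction
  fit <- suppressWarnings(fit_mh(y, cov, n_iter = 8000, burn_in = 3000,
                                 seed = 2))
  post <- colMeans(fit$draws)[1:6]
  expect_lt(max(abs(post - alpha)), 1e-3)
})

test_that("posterior means agree with the flat-prior least-squares center", {
  # conjugate limit: alpha | y is multivariate-t centered on the LS fit
  st <- small_study()
  cov <- st$covariates[st$covariates$year %in% 1950:2005, ]
  X <- design_matrix(cov)
  truth56 <- synthetic_truth(years = 1950:2005, seed = 3)
  gb <- simulate_group_bai(truth56, cov, "spruce_M", seed = 5)
  y <- gb$bai_cm2
  b_ls <- solve(crossprod(X), crossprod(X, y))  # independent closed form
  fit <- fit_mh(y, cov, n_iter = 20000, burn_in = 5000, seed = 12)
  s <- summary(fit)
  for (j in 1:6) {
    expect_lt(abs(s$mean[j] - b_ls[j]), 3 * s$sd[j])
  }
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_equal(nrow(fit$draws), 15000L)
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.6))
})

test_that("chains are reproducible under a fixed seed", {
  cov <- sim_covariates()
  set.seed(20)
  y <- 3 + rnorm(56, 0, 0.4)
  f1 <- fit_mh(y, cov, n_iter = 3000, burn_in = 1000, seed = 5)
  f2 <- fit_mh(y, cov, n_iter = 3000, burn_in = 1000, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mh(y, cov, n_iter = 3000, burn_in = 1000, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior spread tracks the residual noise level", {
  cov <- sim_covariates()
  X <- design_matrix(cov)
  alpha <- c(3, 0, 0.2, -0.1, -0.5, 0.5)
  set.seed(33)
  sd_of <- function(sigma) {
    y <- as.numeric(X %*% alpha) + rnorm(56, 0, sigma)
    fit <- fit_mh(y, cov, n_iter = 8000, burn_in = 3000, seed = 3)
    mean(apply(fit$draws[, 1:6], 2, sd))
  }
  expect_gt(sd_of(0.9), sd_of(0.1))
})

test_that("R-squared matches its definition and the signal/noise split", {
  cov <- sim_covariates()
  X <- design_matrix(cov)
  alpha <- c(3, 0.02, 0, 0, -0.5, 0.5)
  mu <- as.numeric(X %*% alpha)
  fit_perfect <- suppressWarnings(fit_mh(mu + rnorm(56, 0, 1e-6), cov,
                                         n_iter = 4000, burn_in = 2000,
                                         seed = 4))
  expect_gt(r_squared(fit_perfect), 0.999)

  set.seed(77)
  sigma <- 0.4
  y <- mu + rnorm(56, 0, sigma)
  fit <- fit_mh(y, cov, n_iter = 8000, burn_in = 3000, seed = 4)
  r2 <- r_squared(fit)
  expected <- var(mu) / (var(mu) + sigma^2)
  expect_lt(abs(r2 - expected), 0.15)
  expect_lte(r2, 1)

  # predicting the mean explains nothing: R2 near 0 for pure-noise signal
  ynull <- rnorm(56, 5, 0.5)
  fitn <- fit_mh(ynull, cov, n_iter = 6000, burn_in = 2000, seed = 4)
  expect_lt(r_squared(fitn), 0.35)
})

test_that("posterior overlap matches the closed form for shifted normals", {
  set.seed(8)
  a <- rnorm(50000)
  expect_equal(posterior_overlap(a, a)$overlap, 1)
  expect_false(posterior_overlap(a, a)$significant)

  b <- rnorm(50000, 5, 1)
  ov <- posterior_overlap(a, b)
  expect_lt(abs(ov$overlap - 2 * pnorm(-2.5)), 0.02)
  expect_true(ov$significant)

  disj <- posterior_overlap(runif(2000, 0, 1), runif(2000, 10, 11))
  expect_equal(disj$overlap, 0)
  expect_true(disj$significant)

  # symmetric and invariant to a common affine transform
  x <- rnorm(5000); y <- rnorm(5000, 1.5, 1.2)
  o1 <- posterior_overlap(x, y)$overlap
  expect_equal(posterior_overlap(y, x)$overlap, o1, tolerance = 1e-12)
  o2 <- posterior_overlap(3 * x - 2, 3 * y - 2)$overlap
  expect_lt(abs(o1 - o2), 0.03)
  expect_error(posterior_overlap(numeric(0), x), "empty")
})

test_that("convergence diagnostics flag short and bimodal chains", {
  cov <- sim_covariates()
  set.seed(50)
  y <- 3 - 0.4 * cov$sbw + rnorm(56, 0, 0.3)
  fit <- fit_mh(y, cov, n_iter = 20000, burn_in = 5000, seed = 9)
  rep_ok <- convergence_report(fit)
  expect_true(all(rep_ok$stable))
  expect_true(all(rep_ok$unimodal))
  expect_true(all(rep_ok$shrinkage < 0.5))

  short <- convergence_report(fit$draws[1:10, , drop = FALSE],
                              bounds = fit$bounds)
  expect_false(all(short$stable))

  bim <- cbind(alpha = c(rnorm(3000, -4), rnorm(3000, 4)))
  bounds <- rbind(lower = -20, upper = 20)
  expect_false(convergence_report(bim, bounds = bounds)$unimodal)
})

test_that("singular designs warn and remain prior-dominated", {
  cov <- flat_covariates()
  cov$season_length <- cov$summer_heat  # perfectly confounded columns
  set.seed(60)
  y <- 3 + rnorm(56, 0, 0.3)
  w <- capture_warnings(fit_mh(y, cov, n_iter = 2000, burn_in = 500,
                               seed = 2))
  expect_true(any(grepl("singular", w)))
  # unidentified coefficients roam the prior, so bounds are reported too
  expect_true(any(grepl("bounds may bind", w)))
  expect_error(fit_mh(rep(1, 56), flat_covariates(), n_iter = 1000,
                      burn_in = 100), "zero-variance")
})
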