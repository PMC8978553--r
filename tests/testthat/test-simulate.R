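test_that("a fixed seed reproduces the simulation bit-identically", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_shifted_pair(cfg)
  s2 <- simulate_shifted_pair(cfg)
  expect_identical(s1, s2)
  d1 <- simulate_drift_series(sim_config(n_frames = 500, seed = 99),
                              function(f) cbind(0.01 * f, 0 * f))
  d2 <- simulate_drift_series(sim_config(n_frames = 500, seed = 99),
                              function(f) cbind(0.01 * f, 0 * f))
  expect_identical(d1, d2)
})

test_that("localization counts match the Poisson closed form", {
  # expected localizations per data set = density * pi * R^2 * mean_locs
  cfg <- sim_config(density = 5, mean_locs = 2, cell_radius = 5)
  expected <- 5 * pi * 25 * 2
  set.seed(41)
  n <- replicate(40, {
    cfg$seed <- sample.int(1e6, 1)
    nrow(simulate_shifted_pair(cfg)$A)
  })
  # total count is Poisson(expected): mean within 5 SE
  expect_lt(abs(mean(n) - expected), 5 * sqrt(expected / 40))
})

test_that("shift_max = 0 gives a zero true shift; magnitudes stay in range", {
  s <- simulate_shifted_pair(sim_config(shift_max = 0, seed = 1))
  expect_equal(s$true_shift, c(0, 0))
  set.seed(43)
  mags <- replicate(50, {
    cfg <- sim_config(seed = sample.int(1e6, 1))
    sqrt(sum(simulate_shifted_pair(cfg)$true_shift^2))
  })
  expect_true(all(mags >= 0 & mags <= 150))
})

test_that("3D simulation fills a cylinder with anisotropic noise", {
  cfg <- sim_config(dim = 3, density = 20, mean_locs = 2, sigma_z = 30,
                    cell_height = 1, seed = 47)
  sim <- simulate_shifted_pair(cfg)
  expect_equal(loc_dim(sim$A), 3L)
  expect_length(sim$true_shift, 3)
  r <- sqrt(sim$A$x^2 + sim$A$y^2)
  expect_lt(max(r), 5000 + 6 * 15)          # radial extent + noise
  expect_lt(max(abs(sim$A$z)), 500 + 6 * 30) # half-height + noise
})

test_that("the noiseless dense limit recovers the true shift", {
  cfg <- sim_config(density = 0.5, mean_locs = 40, sigma_xy = 1e-4,
                    seed = 53)
  sim <- simulate_shifted_pair(cfg)
  est <- mean_shift(sim$A, sim$B, ms_params(tol = 1e-6))
  expect_equal(est$shift, sim$true_shift, tolerance = 1e-3)
})

test_that("center_of_mass_shift is the difference of centroids", {
  set.seed(59)
  A <- random_points(30, 2)
  t <- c(12, -5)
  expect_equal(center_of_mass_shift(A, sweep(A, 2, -t)), t)
  expect_equal(center_of_mass_shift(matrix(c(1, 2), 1),
                                    matrix(c(4, 7), 1)), c(3, 5))
  expect_error(center_of_mass_shift(A[0, ], A), "non-empty")
})

test_that("blink_corr = 1 gives single-frame blinks; > 1 gives runs", {
  # near-zero noise so localizations of one molecule share coordinates
  cfg <- sim_config(mean_locs = 10, n_frames = 2000, blink_corr = 1,
                    sigma_xy = 1e-6, seed = 61)
  s1 <- simulate_drift_series(cfg, function(f) cbind(0 * f, 0 * f))
  cfg$blink_corr <- 5
  s5 <- simulate_drift_series(cfg, function(f) cbind(0 * f, 0 * f))
  run_score <- function(tab) {
    o <- order(round(tab$x), tab$frame)  # group by molecule, then time
    mean(diff(tab$frame[o]) == 1)
  }
  expect_gt(nrow(s5$table), 100)
  expect_gt(run_score(s5$table), run_score(s1$table))
})

test_that("precision_from_errors recovers a known Gaussian width", {
  set.seed(67)
  s0 <- 6
  errs <- rnorm(4000, 0, s0)
  expect_equal(precision_from_errors(errs, sigma = 15), s0,
               tolerance = 0.05)
  # 10% uniform outliers do not move the central-peak width
  mix <- c(rnorm(3600, 0, s0), runif(400, -60, 60))
  expect_equal(precision_from_errors(mix, sigma = 15), s0,
               tolerance = 0.1)
  # degenerate: all-zero errors fall back to the sample SD of 0
  expect_warning(p0 <- precision_from_errors(rep(0, 100), 15))
  expect_equal(p0, 0)
})

test_that("failure_rate counts any-axis excursions beyond 2 sigma", {
  expect_equal(failure_rate(matrix(0, 10, 2), 15), 0)
  expect_equal(failure_rate(matrix(c(45, 0), 10, 2, byrow = TRUE), 15), 1)
  # closed form: per-axis N(0, (sigma/2)^2), threshold 2 sigma = 4 SD
  p_axis <- 2 * pnorm(-4)
  p_2d <- 1 - (1 - p_axis)^2
  set.seed(71)
  errs <- matrix(rnorm(2e5 * 2, 0, 7.5), ncol = 2)
  expect_lt(abs(failure_rate(errs, 15) - p_2d), 1.5e-4)
})

test_that("benchmark precision degrades from the easy to the hard case", {
  grid <- benchmark_grid(densities = c(5, 20),
                         mean_locs_list = c(2, 0.05),
                         n_reps = 60, seed = 73)
  easy <- grid[grid$density == 5 & grid$mean_locs == 2, ]
  hard <- grid[grid$density == 20 & grid$mean_locs == 0.05, ]
  expect_lt(easy$precision, 15)             # well below sigma
  expect_equal(easy$failure_rate, 0)
  expect_gt(hard$precision, easy$precision)
  expect_gt(hard$failure_rate, 0)
  expect_gt(hard$mean_est_err, easy$mean_est_err)
})
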