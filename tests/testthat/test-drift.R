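test_that("bin_frames partitions frames with the remainder in the last bin", {
  b <- bin_frames(100, 25)
  expect_equal(b$K, 4L)
  expect_equal(b$edges[, "start"], c(1, 26, 51, 76), ignore_attr = TRUE)
  expect_equal(b$edges[, "end"], c(26, 51, 76, 101), ignore_attr = TRUE)
  expect_equal(b$centers, c(13, 38, 63, 88))

  b2 <- bin_frames(105, 25)
  expect_equal(b2$K, 4L)
  expect_equal(b2$edges[4, ], c(start = 76, end = 106))

  expect_error(bin_frames(30, 20), "fewer than 2")
})

test_that("overlapping binning produces half-shifted bins", {
  b <- bin_frames(100, 20, overlap = 0.5)
  expect_equal(b$edges[, "start"], seq(1, 81, by = 10), ignore_attr = TRUE)
  expect_true(all(diff(b$centers) == 10))
})

test_that("pairwise shifts recover an exact per-bin translation", {
  # disjoint molecule sets per bin pair would need no redundancy; here all
  # bins share the same molecules, translated by a known per-bin offset
  set.seed(21)
  # molecules on a coarse grid (800 nm spacing) so the only in-window
  # pairs are same-molecule pairs and recovery is exact
  g <- expand.grid(x = seq(0, 7200, by = 800), y = seq(0, 7200, by = 800))
  mol <- as.matrix(g) + matrix(runif(nrow(g) * 2, -100, 100), nrow(g), 2)
  d_true <- rbind(c(0, 0), c(12, -7), c(30, 5))
  tabs <- lapply(1:3, function(k) {
    p <- sweep(mol, 2, d_true[k, ], `+`)
    loc_table(frame = rep(10 * (k - 1) + 1:10, length.out = nrow(p)),
              x = p[, 1], y = p[, 2])
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("loc_table", "data.frame")
  binning <- bin_frames(30, 10)
  psm <- pairwise_shifts(tab, binning, ms_params(min_pairs = 2, tol = 1e-9))
  for (m in seq_along(psm$i)) {
    tru <- d_true[psm$j[m], ] - d_true[psm$i[m], ]
    expect_equal(psm$shift[m, ], tru, tolerance = 1e-6)
  }
  # K = 2 reduces to a single mean shift of the two halves
  b2 <- bin_frames(30, 15)
  psm2 <- pairwise_shifts(tab, b2, ms_params(min_pairs = 2, tol = 1e-9))
  expect_equal(length(psm2$i), 1L)
})

test_that("fit_trajectory solves exactly for consistent inputs", {
  set.seed(23)
  K <- 6
  d_true <- cbind(cumsum(runif(K, -5, 10)), cumsum(runif(K, -5, 10)))
  d_true <- sweep(d_true, 2, d_true[1, ])
  pairs <- t(combn(K, 2))
  psm <- structure(list(
    K = K, dim = 2, i = pairs[, 1], j = pairs[, 2],
    shift = d_true[pairs[, 2], ] - d_true[pairs[, 1], ],
    err = matrix(runif(nrow(pairs) * 2, 0.5, 3), nrow(pairs), 2),
    n_pairs = rep(100L, nrow(pairs)), n_iter = rep(2L, nrow(pairs)),
    converged = rep(TRUE, nrow(pairs)), valid = rep(TRUE, nrow(pairs))),
    class = "pairwise_shifts")
  binning <- bin_frames(K * 100, 100)
  traj <- fit_trajectory(psm, binning)
  expect_equal(traj$d, d_true, tolerance = 1e-10, ignore_attr = TRUE)
  # gauge: adding a constant to all true drifts changes nothing
  psm_g <- psm  # pairwise differences are unchanged by construction
  expect_equal(fit_trajectory(psm_g, binning)$d[1, ], c(0, 0))
})

test_that("redundant paths are combined by weighted least squares", {
  # one axis, K = 3: delta_12 = 10, delta_23 = 10, delta_13 = 26, equal
  # weights; brute-force oracle over the 2 unknowns
  oracle <- optim(c(0, 0), function(d)
    (10 - d[1])^2 + (10 - (d[2] - d[1]))^2 + (26 - d[2])^2,
    method = "BFGS")$par
  expect_equal(oracle, c(12, 24), tolerance = 1e-6)  # frozen oracle value
  psm <- structure(list(
    K = 3, dim = 1, i = c(1, 2, 1), j = c(2, 3, 3),
    shift = matrix(c(10, 10, 26), 3, 1),
    err = matrix(1, 3, 1),
    n_pairs = rep(10L, 3), n_iter = rep(2L, 3),
    converged = rep(TRUE, 3), valid = rep(TRUE, 3)),
    class = "pairwise_shifts")
  traj <- fit_trajectory(psm, bin_frames(300, 100))
  expect_equal(drop(traj$d), c(0, 12, 24), tolerance = 1e-9)
})

test_that("68% confidence intervals are calibrated on heteroscedastic shifts", {
  set.seed(29)
  K <- 5
  pairs <- t(combn(K, 2))
  np <- nrow(pairs)
  d_true <- c(0, 4, 9, 15, 22)
  eps <- matrix(runif(np, 0.5, 4), np, 1)
  hits <- 0; total <- 0
  for (rep in 1:250) {
    delta <- d_true[pairs[, 2]] - d_true[pairs[, 1]] + rnorm(np, 0, eps)
    psm <- structure(list(
      K = K, dim = 1, i = pairs[, 1], j = pairs[, 2],
      shift = matrix(delta, np, 1), err = eps,
      n_pairs = rep(10L, np), n_iter = rep(2L, np),
      converged = rep(TRUE, np), valid = rep(TRUE, np)),
      class = "pairwise_shifts")
    traj <- fit_trajectory(psm, bin_frames(K * 50, 50))
    hit <- abs(drop(traj$d)[-1] - d_true[-1]) <= drop(traj$ci68)[-1]
    hits <- hits + sum(hit); total <- total + (K - 1)
  }
  expect_gt(hits / total, 0.58)
  expect_lt(hits / total, 0.78)
})

test_that("invalid pairs are excluded and disconnection is an error", {
  psm <- structure(list(
    K = 3, dim = 1, i = c(1, 2, 1), j = c(2, 3, 3),
    shift = matrix(c(10, 10, 26), 3, 1), err = matrix(1, 3, 1),
    n_pairs = rep(10L, 3), n_iter = rep(2L, 3),
    converged = rep(TRUE, 3), valid = c(TRUE, FALSE, FALSE)),
    class = "pairwise_shifts")
  expect_error(fit_trajectory(psm, bin_frames(300, 100)), "disconnected")
  psm$valid <- rep(FALSE, 3)
  expect_error(fit_trajectory(psm, bin_frames(300, 100)), "no valid")
})

test_that("exclude_adjacent drops consecutive-bin pairs from the fit", {
  set.seed(31)
  K <- 5
  pairs <- t(combn(K, 2))
  np <- nrow(pairs)
  d_true <- cumsum(c(0, runif(K - 1, 0, 8)))
  delta <- d_true[pairs[, 2]] - d_true[pairs[, 1]] + rnorm(np, 0, 0.5)
  psm <- structure(list(
    K = K, dim = 1, i = pairs[, 1], j = pairs[, 2],
    shift = matrix(delta, np, 1), err = matrix(0.5, np, 1),
    n_pairs = rep(10L, np), n_iter = rep(2L, np),
    converged = rep(TRUE, np), valid = rep(TRUE, np)),
    class = "pairwise_shifts")
  binning <- bin_frames(K * 50, 50)
  full <- fit_trajectory(psm, binning)
  nadj <- fit_trajectory(psm, binning, exclude_adjacent = TRUE)
  # same data, no blinking correlation: fits agree within the CIs
  expect_true(all(abs(full$d - nadj$d) <= full$ci68 + nadj$ci68 + 1e-9))
})

test_that("interpolation is linear with clamped ends", {
  traj <- structure(list(times = c(10, 20), d = rbind(c(0, 0), c(10, -4)),
                         ci68 = matrix(0, 2, 2), dim = 2L),
                    class = "drift_trajectory")
  expect_equal(drop(interpolate_drift(traj, 10)), c(0, 0))
  expect_equal(drop(interpolate_drift(traj, 20)), c(10, -4))
  expect_equal(drop(interpolate_drift(traj, 15)), c(5, -2))
  expect_equal(drop(interpolate_drift(traj, 1)), c(0, 0))      # clamp left
  expect_equal(drop(interpolate_drift(traj, 99)), c(10, -4))   # clamp right
})

test_that("applying a zero trajectory is the identity", {
  set.seed(33)
  tab <- loc_table(frame = 1:50, x = rnorm(50), y = rnorm(50))
  traj <- structure(list(times = c(10, 40), d = matrix(0, 2, 2),
                         ci68 = matrix(0, 2, 2), dim = 2L),
                    class = "drift_trajectory")
  expect_equal(apply_drift_correction(tab, traj), tab)
  traj3 <- structure(list(times = c(10, 40), d = matrix(0, 2, 3),
                          ci68 = matrix(0, 2, 3), dim = 3L),
                     class = "drift_trajectory")
  expect_error(apply_drift_correction(tab, traj3), "dimension mismatch")
})

test_that("linear drift is estimated, removed, and re-estimation finds none", {
  cfg <- sim_config(mean_locs = 20, n_frames = 6000, blink_corr = 2,
                    seed = 37)
  rate <- c(0.008, -0.005)
  sim <- simulate_drift_series(cfg, function(f) cbind(rate[1] * f,
                                                      rate[2] * f))
  traj <- estimate_drift(sim$table, bin_width = 1000,
                         params = ms_params(min_pairs = 5),
                         chisq_rescale = TRUE)
  truth_at <- sim$truth[round(traj$times), ]
  truth_at <- sweep(truth_at, 2, truth_at[1, ])
  # control points track the truth to a few nm (drift spans ~55 nm)
  expect_lt(max(abs(traj$d - truth_at)), 10)

  corr <- apply_drift_correction(sim$table, traj)
  traj2 <- estimate_drift(corr, bin_width = 1000,
                          params = ms_params(min_pairs = 5),
                          chisq_rescale = TRUE)
  expect_lt(max(abs(traj2$d)), max(abs(traj$d - truth_at)) + 3)
  # corrected per-molecule spread approaches the localization noise:
  # net estimated drift is essentially gone relative to what was applied
  expect_lt(sqrt(sum(traj2$d[nrow(traj2$d), ]^2)),
            0.2 * sqrt(sum(traj$d[nrow(traj$d), ]^2)))
})
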