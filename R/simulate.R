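#' Benchmark simulation configuration
#'
#' Describes the synthetic test specimen and imaging statistics used by the
#' benchmark generators: a circular test cell (2D) or cylindrical volume
#' (3D) of uniformly distributed molecules, each localized a Poisson number
#' of times per data set with isotropic-per-axis Gaussian localization
#' noise. Defaults reproduce the easy 2D benchmark condition: 5
#' molecules/um^2, an average of two localizations per molecule, 15 nm
#' lateral precision, and random shifts of magnitude 0-150 nm (10 sigma).
#'
#' @param dim 2 or 3.
#' @param density molecules per um^2 of footprint area.
#' @param mean_locs mean localizations per molecule per data set (for
#'   [simulate_drift_series()]: over the whole series).
#' @param sigma_xy lateral localization precision, nm.
#' @param sigma_z axial precision, nm (3D; typically ~2x lateral).
#' @param cell_radius test-cell radius, um.
#' @param cell_height cylinder height, um (3D).
#' @param shift_max maximum shift magnitude, nm; the true shift magnitude
#'   is Uniform(0, shift_max) with uniformly random direction.
#' @param shift_mode `"magnitude"` (uniform magnitude, random direction;
#'   default) or `"component"` (each component Uniform(-shift_max, shift_max)).
#' @param n_frames number of acquisition frames for drift series.
#' @param blink_corr mean length (frames) of a molecule's consecutive-frame
#'   localization runs; 1 means independent single-frame blinks.
#' @param seed optional RNG seed; a fixed seed makes outputs bit-identical.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(dim = 2, density = 5, mean_locs = 2, sigma_xy = 15,
                       sigma_z = 30, cell_radius = 5, cell_height = 1,
                       shift_max = 150, shift_mode = c("magnitude", "component"),
                       n_frames = 10000, blink_corr = 1, seed = NULL) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(dim %in% c(2, 3), density > 0, mean_locs > 0, sigma_xy > 0,
            sigma_z > 0, cell_radius > 0, cell_height > 0, shift_max >= 0,
            n_frames >= 1, blink_corr >= 1)
  structure(list(dim = as.integer(dim), density = density,
                 mean_locs = mean_locs, sigma_xy = sigma_xy,
                 sigma_z = sigma_z, cell_radius = cell_radius,
                 cell_height = cell_height, shift_max = shift_max,
                 shift_mode = shift_mode, n_frames = as.integer(n_frames),
                 blink_corr = blink_corr, seed = seed),
            class = "sim_config")
}

# uniform molecule positions in the test cell, in nm
.draw_molecules <- function(config) {
  R <- config$cell_radius * 1000
  n <- rpois(1, config$density * pi * config$cell_radius^2)
  r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  if (config$dim == 3)
    pos <- cbind(pos, z = runif(n, -config$cell_height * 500,
                                config$cell_height * 500))
  pos
}

.loc_noise <- function(n, config) {
  s <- c(config$sigma_xy, config$sigma_xy,
         if (config$dim == 3) config$sigma_z)
  matrix(rnorm(n * config$dim), n, config$dim) %*% diag(s, config$dim)
}

.draw_shift <- function(config) {
  d <- config$dim
  if (config$shift_mode == "component")
    return(runif(d, -config$shift_max, config$shift_max))
  if (config$shift_max == 0) return(rep(0, d))
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  runif(1, 0, config$shift_max) * u
}

# sample one data set: Poisson(mean_locs) localizations per molecule
.sample_locs <- function(mol, config, offset = NULL) {
  counts <- rpois(nrow(mol), config$mean_locs)
  idx <- rep.int(seq_len(nrow(mol)), counts)
  n <- length(idx)
  pos <- mol[idx, , drop = FALSE]
  if (!is.null(offset)) pos <- sweep(pos, 2, offset, `+`)
  pos + .loc_noise(n, config)
}

#' Simulate a pair of localization sets with a known relative shift
#'
#' Generates the shifted-pair benchmark: molecules uniform over the test
#' cell, two independent samplings (Poisson localizations per molecule,
#' Gaussian noise), the second with its molecules translated by a random
#' true shift. Fully reproducible under a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `A`, `B` (two [loc_table()]s, all frames = 1) and
#'   `true_shift` (d-vector, nm).
#' @examples
#' sim <- simulate_shifted_pair(sim_config(seed = 1))
#' mean_shift(sim$A, sim$B)$shift - sim$true_shift
#' @export
simulate_shifted_pair <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mol <- .draw_molecules(config)
  true_shift <- .draw_shift(config)
  pa <- .sample_locs(mol, config)
  pb <- .sample_locs(mol, config, offset = true_shift)
  mk <- function(p) loc_table(frame = rep(1L, nrow(p)), x = p[, 1],
                              y = p[, 2],
                              z = if (config$dim == 3) p[, 3],
                              precision = rep(config$sigma_xy, nrow(p)))
  list(A = mk(pa), B = mk(pb), true_shift = true_shift)
}

#' Simulate a continuously drifting acquisition with blinking emitters
#'
#' Generates a full time series: each molecule turns on in runs of
#' consecutive frames (geometric run length with mean `blink_corr`,
#' modelling the finite off-rate of fluorophore blinking/binding), and each
#' emitted localization is the molecule position plus the drift at its
#' frame plus Gaussian noise. `mean_locs` is the expected number of
#' localizations per molecule over the whole series.
#'
#' @param config a [sim_config()].
#' @param drift_curve function mapping a vector of frame indices to a
#'   matrix of drift vectors (nm), one row per frame.
#' @return list with `table` (a [loc_table()]) and `truth` (n_frames x dim
#'   matrix of the exact drift applied at each frame).
#' @export
simulate_drift_series <- function(config = sim_config(),
                                  drift_curve) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mol <- .draw_molecules(config)
  nmol <- nrow(mol)
  F <- config$n_frames
  truth <- drift_curve(seq_len(F))
  truth <- matrix(as.numeric(truth), nrow = F)
  if (ncol(truth) != config$dim)
    stop("drift_curve must return ", config$dim, " columns")
  # blink runs: Poisson number of runs, geometric lengths of mean blink_corr
  n_runs <- rpois(nmol, config$mean_locs / config$blink_corr)
  mol_id <- rep.int(seq_len(nmol), n_runs)
  nr <- length(mol_id)
  starts <- sample.int(F, nr, replace = TRUE)
  lens <- 1L + rgeom(nr, prob = 1 / config$blink_corr)
  frames <- integer(0); ids <- integer(0)
  if (nr > 0) {
    lens <- pmin(lens, F - starts + 1L)
    ids <- rep.int(mol_id, lens)
    frames <- unlist(lapply(seq_len(nr),
                            function(m) seq.int(starts[m],
                                                length.out = lens[m])),
                     use.names = FALSE)
  }
  n <- length(frames)
  pos <- mol[ids, , drop = FALSE] + truth[frames, , drop = FALSE] +
    .loc_noise(n, config)
  ord <- order(frames)
  tab <- loc_table(frame = frames[ord], x = pos[ord, 1], y = pos[ord, 2],
                   z = if (config$dim == 3) pos[ord, 3],
                   precision = rep(config$sigma_xy, n))
  list(table = tab, truth = truth)
}

#' Center-of-mass shift baseline
#'
#' The naive shift estimate: difference of the two data sets' centers of
#' mass. Orders of magnitude less precise than the mean shift because
#' every localization — not just re-localized molecules — contributes its
#' full positional variance.
#'
#' @param A,B point sets (matrices or [loc_table()]s), non-empty.
#' @return d-vector, `colMeans(B) - colMeans(A)`.
#' @export
center_of_mass_shift <- function(A, B) {
  A <- loc_coords(A); B <- loc_coords(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty")
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets")
  colMeans(B) - colMeans(A)
}

#' Precision as the SD of a Gaussian fit to the central error peak
#'
#' Benchmark precision metric: histogram the per-axis signed errors (bin
#' width sigma/5 over +/- 4 sigma) and least-squares fit
#' `A * exp(-e^2 / 2 s^2) + c`, returning `s`. Fitting the central peak
#' rather than taking the raw SD makes the metric robust to the heavy
#' tails contributed by failed estimates.
#'
#' @param errors numeric vector of signed per-axis errors, nm (>= 50).
#' @param sigma localization precision, nm (sets the histogram scale).
#' @return fitted peak SD in nm.
#' @export
precision_from_errors <- function(errors, sigma) {
  stopifnot(length(errors) >= 50, sigma > 0)
  errors <- errors[is.finite(errors)]
  breaks <- seq(-4 * sigma, 4 * sigma, by = sigma / 5)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- tabulate(findInterval(errors, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(mids))
  if (sum(counts > 0) < 3) {
    warning("degenerate error histogram; returning sample SD")
    return(sd(errors))
  }
  core <- abs(errors) <= 2 * sigma
  s0 <- if (sum(core) > 2) max(sd(errors[core]), sigma / 50) else sigma / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ A * exp(-mids^2 / (2 * s^2)) + c0,
                      start = list(A = max(counts), s = s0,
                                   c0 = min(counts)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian peak fit failed; returning sample SD")
    return(sd(errors))
  }
  abs(unname(stats::coef(fit)["s"]))
}

#' Failure rate of shift estimates
#'
#' Fraction of replicates whose error exceeds twice the localization
#' precision on any axis.
#'
#' @param errors numeric matrix of signed errors (rows = replicates,
#'   columns = axes) or a vector (1 axis).
#' @param sigma localization precision, nm; scalar or per-axis vector.
#' @return fraction in `[0, 1]`.
#' @export
failure_rate <- function(errors, sigma) {
  errors <- as.matrix(errors)
  stopifnot(nrow(errors) >= 1)
  if (length(sigma) == 1) sigma <- rep(sigma, ncol(errors))
  stopifnot(length(sigma) == ncol(errors))
  fail <- apply(abs(errors) > 2 * rep(sigma, each = nrow(errors)), 1, any)
  fail[!is.finite(rowSums(errors))] <- TRUE
  mean(fail)
}

#' Benchmark the mean-shift estimator over a condition grid
#'
#' For each (density, mean localizations per molecule) cell, simulates
#' `n_reps` shifted pairs, estimates the shift by [mean_shift()] (and
#' optionally by [center_of_mass_shift()]), and scores precision (Gaussian
#' peak SD of pooled per-axis errors), failure rate (any-axis error > 2
#' sigma), and the replicate-mean estimated error (RMS of the per-axis
#' error estimates) — the data-driven reliability proxy whose sigma/4
#' threshold guides the choice of temporal bin width.
#'
#' @param densities numeric vector of molecule densities (per um^2).
#' @param mean_locs_list numeric vector of mean localizations/molecule.
#' @param n_reps replicates per cell (>= 50).
#' @param config base [sim_config()]; density/mean_locs are overridden.
#' @param params [ms_params()] for the estimator.
#' @param include_com also score the center-of-mass baseline.
#' @param seed base seed; each (cell, replicate) derives a distinct
#'   sub-seed so different base seeds give non-overlapping streams.
#' @return data.frame with one row per cell: density, mean_locs,
#'   precision, failure_rate, mean_est_err, valid_frac, runtime (s), and
#'   (if requested) com_precision, com_failure_rate; the per-replicate
#'   per-axis errors are attached as attribute `"errors"` (list of
#'   matrices).
#' @export
benchmark_grid <- function(densities, mean_locs_list, n_reps = 100,
                           config = sim_config(), params = ms_params(),
                           include_com = FALSE, seed = 1) {
  stopifnot(n_reps >= 50)
  grid <- expand.grid(density = densities, mean_locs = mean_locs_list)
  res <- vector("list", nrow(grid))
  errs_out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$density <- grid$density[g]
    cfg$mean_locs <- grid$mean_locs[g]
    errs <- matrix(NA_real_, n_reps, cfg$dim)
    com_errs <- if (include_com) matrix(NA_real_, n_reps, cfg$dim)
    est_err <- rep(NA_real_, n_reps)
    ok <- logical(n_reps)
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(n_reps)) {
      cfg$seed <- (seed %% 20000L) * 100000L + g * 10000L + r
      sim <- simulate_shifted_pair(cfg)
      if (nrow(sim$A) == 0 || nrow(sim$B) == 0) next  # counted as failure
      est <- mean_shift(sim$A, sim$B, params)
      errs[r, ] <- est$shift - sim$true_shift
      est_err[r] <- sqrt(mean(est$err^2))
      ok[r] <- est$valid
      if (include_com)
        com_errs[r, ] <- center_of_mass_shift(sim$A, sim$B) - sim$true_shift
    }
    runtime <- (proc.time()[["elapsed"]] - t0) / n_reps
    sig <- c(cfg$sigma_xy, cfg$sigma_xy,
             if (cfg$dim == 3) cfg$sigma_z)
    row <- data.frame(
      density = cfg$density, mean_locs = cfg$mean_locs,
      # precision over the lateral axes; failure thresholds per axis
      precision = precision_from_errors(as.vector(errs[, 1:2]),
                                        cfg$sigma_xy),
      failure_rate = failure_rate(errs, sig),
      mean_est_err = if (any(is.finite(est_err)))
        mean(est_err[is.finite(est_err)]) else NA_real_,
      valid_frac = mean(ok), runtime = runtime)
    if (include_com) {
      row$com_precision <- sd(as.vector(com_errs[, 1:2]))
      row$com_failure_rate <- failure_rate(com_errs, sig)
    }
    res[[g]] <- row
    errs_out[[g]] <- errs
  }
  out <- do.call(rbind, res)
  attr(out, "errors") <- errs_out
  out
}
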