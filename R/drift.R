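#' Partition acquisition frames into temporal bins
#'
#' Drift is resolved in time by pooling localizations into contiguous
#' temporal bins of equal frame count; each bin becomes one point set and
#' one control point of the drift trajectory. By default bins do not
#' overlap and any trailing remainder frames are folded into the last bin
#' so no localization is discarded.
#'
#' `overlap > 0` produces overlapping bins (e.g. 0.5 for half-overlapping)
#' and exists for diagnostics only: shift estimates between overlapping
#' bins share localizations and are biased toward zero, so overlapping
#' binning systematically underestimates accrued drift and is not used for
#' correction.
#'
#' @param F_max total number of acquisition frames (>= 2 * bin_width).
#' @param bin_width frames per bin (>= 2).
#' @param overlap fractional overlap between consecutive bins in `[0, 1)`;
#'   default 0 (non-overlapping).
#' @return Object of class `"temporal_binning"`: list with `bin_width`,
#'   `K`, `edges` (K x 2 matrix of half-open frame intervals
#'   `[start, end)`), `centers` (frame midpoints), `overlap`.
#' @examples
#' bin_frames(100, 25)$edges
#' bin_frames(105, 25)$edges  # remainder folds into the last bin
#' @export
bin_frames <- function(F_max, bin_width, overlap = 0) {
  stopifnot(bin_width >= 2, overlap >= 0, overlap < 1)
  F_max <- as.integer(F_max); bin_width <- as.integer(bin_width)
  if (F_max < 2 * bin_width)
    stop("fewer than 2 full bins: F_max = ", F_max,
         ", bin_width = ", bin_width)
  if (overlap == 0) {
    K <- F_max %/% bin_width
    starts <- 1L + (seq_len(K) - 1L) * bin_width
    ends <- starts + bin_width
    ends[K] <- F_max + 1L   # absorb remainder frames
  } else {
    step <- max(1L, as.integer(round(bin_width * (1 - overlap))))
    starts <- seq.int(1L, F_max - bin_width + 1L, by = step)
    ends <- starts + bin_width
    K <- length(starts)
    if (K < 2) stop("fewer than 2 bins: F_max = ", F_max)
  }
  structure(list(bin_width = bin_width, K = as.integer(K),
                 edges = cbind(start = starts, end = ends),
                 centers = (starts + ends - 1) / 2,
                 overlap = overlap),
            class = "temporal_binning")
}

#' Estimate shifts between all pairs of temporal bins
#'
#' Runs [mean_shift()] between the localization sets of every bin pair
#' `i < j`, tabulating the shift estimate and its per-axis error. This
#' redundancy — all K(K-1)/2 pairs rather than only consecutive ones —
#' overdetermines the K control points and is what gives the weighted
#' least-squares trajectory its precision.
#'
#' @param table a [loc_table()].
#' @param binning a [bin_frames()] result.
#' @param params an [ms_params()].
#' @param start_traj optional `"drift_trajectory"` from a first coarse
#'   pass; when given, the mean shift for pair (i, j) is seeded from the
#'   trajectory difference between the bin centers (for very large drift).
#' @return Object of class `"pairwise_shifts"`: list with `K`, `dim`, and
#'   per-pair vectors/matrices `i`, `j`, `shift`, `err`, `n_pairs`,
#'   `converged`, `valid`. Pairs involving an empty bin are flagged
#'   invalid, not fatal. Per-axis errors are floored at 1e-6 nm so exact
#'   estimates keep finite least-squares weight.
#' @export
pairwise_shifts <- function(table, binning, params = ms_params(),
                            start_traj = NULL) {
  validate_loc_table(table)
  d <- loc_dim(table)
  K <- binning$K
  coords <- loc_coords(table)
  bins <- lapply(seq_len(K), function(k) {
    sel <- table$frame >= binning$edges[k, 1] & table$frame < binning$edges[k, 2]
    coords[sel, , drop = FALSE]
  })
  np <- K * (K - 1) / 2
  ii <- jj <- integer(np)
  shift <- err <- matrix(NA_real_, np, d)
  n_pairs <- n_iter <- integer(np)
  converged <- valid <- logical(np)
  m <- 0L
  for (i in seq_len(K - 1)) {
    for (j in seq.int(i + 1, K)) {
      m <- m + 1L
      ii[m] <- i; jj[m] <- j
      if (nrow(bins[[i]]) == 0 || nrow(bins[[j]]) == 0) next  # invalid
      start <- if (is.null(start_traj)) rep(0, d) else
        drop(interpolate_drift(start_traj, binning$centers[j]) -
             interpolate_drift(start_traj, binning$centers[i]))
      est <- mean_shift(bins[[i]], bins[[j]], params, start = start)
      shift[m, ] <- est$shift
      err[m, ] <- pmax(est$err, 1e-6)
      n_pairs[m] <- est$n_pairs; n_iter[m] <- est$n_iter
      converged[m] <- est$converged; valid[m] <- est$valid
    }
  }
  structure(list(K = K, dim = d, i = ii, j = jj, shift = shift, err = err,
                 n_pairs = n_pairs, n_iter = n_iter,
                 converged = converged, valid = valid),
            class = "pairwise_shifts")
}

#' Fit a drift trajectory through bin control points
#'
#' Combines all valid pairwise bin shifts into per-bin drift control
#' points by error-weighted linear least squares. Each axis decouples: for
#' axis k the model is `shift_ij = d_j - d_i` with weight `1 / err_ij^2`,
#' anchored by the gauge convention `d_1 = 0`. The 68% confidence
#' half-widths are the square roots of the diagonal of the inverse
#' weighted normal matrix; weights are treated as absolute inverse
#' variances (no a-posteriori chi-square rescaling) unless
#' `chisq_rescale = TRUE`.
#'
#' @param psm a [pairwise_shifts()] result.
#' @param binning the [bin_frames()] result the shifts were computed on.
#' @param exclude_adjacent drop pairs of adjacent bins (`j = i + 1`) before
#'   solving — a diagnostic for bias from time-correlated blinking.
#' @param chisq_rescale rescale CIs by the reduced chi-square of the fit.
#' @param max_rms_err optional gate: pairs whose root-mean-square per-axis
#'   error exceeds this value (nm) are dropped. The sigma/4 rule of thumb —
#'   the mean shift loses robustness once its estimated error exceeds a
#'   quarter of the localization precision — suggests `sigma / 4`.
#' @return Object of class `"drift_trajectory"`: list with `times` (bin
#'   center frames), `d` (K x dim control-point drifts, nm, `d[1, ] = 0`),
#'   `ci68` (K x dim 68% half-widths, nm), `dim`.
#' @export
fit_trajectory <- function(psm, binning, exclude_adjacent = FALSE,
                           chisq_rescale = FALSE, max_rms_err = NULL) {
  K <- psm$K
  keep <- psm$valid
  if (exclude_adjacent) keep <- keep & (psm$j != psm$i + 1L)
  if (!is.null(max_rms_err))
    keep <- keep & sqrt(rowMeans(psm$err^2)) <= max_rms_err
  if (!any(keep)) stop("no valid pairwise shift estimates to fit")
  i <- psm$i[keep]; j <- psm$j[keep]
  .check_connected(i, j, K)
  d <- psm$dim
  D <- matrix(0, K, d); CI <- matrix(0, K, d)
  # design matrix over unknowns d_2..d_K (d_1 = 0 fixes the gauge)
  X <- matrix(0, length(i), K - 1)
  for (m in seq_along(i)) {
    if (i[m] > 1) X[m, i[m] - 1] <- -1
    X[m, j[m] - 1] <- 1
  }
  for (k in seq_len(d)) {
    y <- psm$shift[keep, k]
    w <- 1 / psm$err[keep, k]^2
    XtWX <- crossprod(X * sqrt(w))
    cov <- solve(XtWX)
    dhat <- drop(cov %*% crossprod(X, w * y))
    if (chisq_rescale) {
      dof <- length(y) - (K - 1)
      if (dof > 0) {
        chi2 <- sum(w * (y - drop(X %*% dhat))^2)
        cov <- cov * max(chi2 / dof, .Machine$double.eps)
      }
    }
    D[2:K, k] <- dhat
    CI[2:K, k] <- sqrt(diag(cov))
  }
  structure(list(times = binning$centers, d = D, ci68 = CI, dim = d),
            class = "drift_trajectory")
}

.check_connected <- function(i, j, K) {
  adj <- vector("list", K)
  for (m in seq_along(i)) {
    adj[[i[m]]] <- c(adj[[i[m]]], j[m])
    adj[[j[m]]] <- c(adj[[j[m]]], i[m])
  }
  seen <- logical(K); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  if (!all(seen))
    stop("pair graph is disconnected; unreachable bins: ",
         paste(which(!seen), collapse = ", "))
  invisible(TRUE)
}

#' Interpolate a drift trajectory at arbitrary frames
#'
#' Linear interpolation between bracketing control points; constant
#' (clamped) extrapolation before the first and after the last control
#' time.
#'
#' @param traj a `"drift_trajectory"`.
#' @param frames integer vector of frame indices (>= 1).
#' @return numeric matrix, `length(frames)` x dim, of drift vectors in nm.
#' @export
interpolate_drift <- function(traj, frames) {
  stopifnot(all(frames >= 1))
  out <- matrix(0, length(frames), traj$dim)
  for (k in seq_len(traj$dim))
    out[, k] <- approx(traj$times, traj$d[, k], xout = frames,
                       rule = 2)$y
  out
}

#' Subtract an estimated drift trajectory from a localization table
#'
#' Each localization's coordinates become `raw - drift(frame)`; frames,
#' precisions and row order are unchanged.
#'
#' @param table a [loc_table()].
#' @param traj a `"drift_trajectory"` of the same dimension.
#' @return the corrected [loc_table()].
#' @export
apply_drift_correction <- function(table, traj) {
  validate_loc_table(table)
  if (traj$dim != loc_dim(table))
    stop("dimension mismatch: trajectory is ", traj$dim, "D, table is ",
         loc_dim(table), "D")
  corr <- interpolate_drift(traj, table$frame)
  table$x <- table$x - corr[, 1]
  table$y <- table$y - corr[, 2]
  if (traj$dim == 3) table$z <- table$z - corr[, 3]
  table
}

#' One-call drift estimation
#'
#' Convenience wrapper: bins the table, estimates all pairwise bin shifts
#' by mean shift, and fits the weighted least-squares trajectory.
#'
#' @inheritParams pairwise_shifts
#' @inheritParams fit_trajectory
#' @param bin_width frames per temporal bin.
#' @param two_pass if `TRUE`, refine with a second pairwise pass seeded
#'   from the first trajectory (for very large drift).
#' @return a `"drift_trajectory"`, with the `"pairwise_shifts"` object
#'   attached as attribute `"psm"`.
#' @examples
#' sim <- simulate_drift_series(
#'   sim_config(cell_radius = 2, n_frames = 2000, mean_locs = 20, seed = 7),
#'   drift_curve = function(f) cbind(0.01 * f, 0))
#' traj <- estimate_drift(sim$table, bin_width = 500,
#'                        params = ms_params(min_pairs = 5))
#' traj$d
#' @export
estimate_drift <- function(table, bin_width, params = ms_params(),
                           exclude_adjacent = FALSE, chisq_rescale = FALSE,
                           max_rms_err = NULL, two_pass = FALSE) {
  binning <- bin_frames(max(table$frame), bin_width)
  psm <- pairwise_shifts(table, binning, params)
  traj <- fit_trajectory(psm, binning, exclude_adjacent = exclude_adjacent,
                         chisq_rescale = chisq_rescale,
                         max_rms_err = max_rms_err)
  if (two_pass) {
    psm <- pairwise_shifts(table, binning, params, start_traj = traj)
    traj <- fit_trajectory(psm, binning, exclude_adjacent = exclude_adjacent,
                           chisq_rescale = chisq_rescale,
                           max_rms_err = max_rms_err)
  }
  attr(traj, "psm") <- psm
  traj
}

#' @export
print.drift_trajectory <- function(x, ...) {
  total <- sqrt(sum((x$d[nrow(x$d), ] - x$d[1, ])^2))
  cat(sprintf("<drift_trajectory> %d control points, %dD, net drift %.2f nm\n",
              length(x$times), x$dim, total))
  invisible(x)
}

#' Plot a drift trajectory with 68% confidence bars
#'
#' @param x a `"drift_trajectory"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.drift_trajectory <- function(x, ...) {
  lab <- c("x", "y", "z")[seq_len(x$dim)]
  graphics::matplot(x$times, x$d, type = "l", lty = 1,
                    xlab = "frame", ylab = "drift [nm]", ...)
  for (k in seq_len(x$dim))
    graphics::arrows(x$times, x$d[, k] - x$ci68[, k],
                     x$times, x$d[, k] + x$ci68[, k],
                     length = 0.02, angle = 90, code = 3, col = k)
  graphics::legend("topleft", legend = lab, col = seq_len(x$dim), lty = 1,
                   bty = "n")
  invisible(x)
}
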