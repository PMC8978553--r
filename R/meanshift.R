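#' Mean-shift parameters
#'
#' Parameters of the iterative mean-shift shift estimator. The first
#' iteration uses the (possibly larger) radius `r_initial`, so shifts of
#' magnitude up to roughly `r_initial - r_window` are captured from a cold
#' start at zero; subsequent iterations use `r_window`. Typical window
#' radii are 100 nm for experimental localizations and 150 nm for
#' simulated benchmarks.
#'
#' @param r_initial first-iteration window radius, nm.
#' @param r_window window radius for subsequent iterations, nm; defaults to
#'   `r_initial` (fixed-radius iteration).
#' @param tol convergence tolerance on the movement of the mean, nm.
#' @param max_iter maximum number of iterations.
#' @param min_pairs minimum in-window pair count for an estimate to be
#'   considered valid.
#' @param scale optional per-axis window scale passed to [cross_pairs()].
#' @return list of class `"ms_params"`.
#' @export
ms_params <- function(r_initial = 150, r_window = r_initial, tol = 0.1,
                      max_iter = 50L, min_pairs = 10L, scale = NULL) {
  stopifnot(r_initial >= r_window, r_window > 0, tol > 0,
            max_iter >= 1, min_pairs >= 1)
  structure(list(r_initial = r_initial, r_window = r_window, tol = tol,
                 max_iter = as.integer(max_iter),
                 min_pairs = as.integer(min_pairs), scale = scale),
            class = "ms_params")
}

#' Estimate the shift between two point sets by iterative mean shift
#'
#' Pairwise displacements between localizations of the same emitter in the
#' two sets cluster around the true relative shift, while displacements
#' between different emitters form a diffuse background. Starting from
#' `start`, each iteration extracts all displacements inside a window
#' centered on the current guess and moves the guess to their centroid; the
#' window is redrawn around the new mean and the process repeats until the
#' mean moves by no more than `tol` (the peak is centered in the window).
#'
#' An iteration window containing fewer than `min_pairs` displacements
#' yields a non-converged estimate flagged invalid (`valid = FALSE`) rather
#' than an error, so callers can drop it.
#'
#' @param A,B point sets (matrices or [loc_table()]s) of equal dimension.
#' @param params an [ms_params()] object.
#' @param start starting shift guess (d-vector, nm); defaults to zero.
#' @return Object of class `"shift_estimate"`: list with `shift` (d-vector,
#'   nm), `err` (per-axis standard error of the final centroid, nm),
#'   `n_pairs`, `n_iter`, `converged`, `valid`.
#' @examples
#' A <- rbind(c(0, 0), c(1000, 0))
#' B <- sweep(A, 2, c(-25, -25))   # A translated by (25, 25)
#' mean_shift(A, B, ms_params(r_initial = 150, min_pairs = 1))$shift
#' @export
mean_shift <- function(A, B, params = ms_params(),
                       start = NULL) {
  A <- loc_coords(A); B <- loc_coords(B)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets")
  d <- ncol(A)
  if (is.null(start)) start <- rep(0, d)
  stopifnot(length(start) == d, all(is.finite(start)))
  mu <- as.double(start)
  converged <- FALSE
  n_iter <- 0L
  dset <- NULL
  for (it in seq_len(params$max_iter)) {
    r <- if (it == 1L) params$r_initial else params$r_window
    dset <- cross_pairs(A, B, mu, r, scale = params$scale)
    n_iter <- it
    if (dset$count < params$min_pairs) {
      return(shift_estimate(mu, rep(NA_real_, d), dset$count, n_iter,
                            converged = FALSE, valid = FALSE))
    }
    mu_new <- colMeans(dset$vectors)
    moved <- sqrt(sum((mu_new - mu)^2))
    mu <- mu_new
    if (moved <= params$tol) { converged <- TRUE; break }
  }
  err <- estimate_error(dset)
  shift_estimate(mu, err, dset$count, n_iter, converged,
                 valid = converged && all(is.finite(err)))
}

#' Per-axis error of the mean in-window displacement
#'
#' The weight and reliability proxy of a mean-shift estimate: the standard
#' error of the centroid of the in-window displacements, computed per axis
#' as SD / sqrt(count). More same-emitter pairs tighten it; more background
#' pairs inflate it. Requires at least two displacements; otherwise the
#' error is undefined (`NA`, flagging the estimate invalid upstream).
#'
#' @param disp a `"displacement_set"` from [cross_pairs()].
#' @return numeric d-vector of per-axis standard errors (nm).
#' @export
estimate_error <- function(disp) {
  stopifnot(inherits(disp, "displacement_set"))
  d <- ncol(disp$vectors)
  if (disp$count < 2) return(rep(NA_real_, d))
  apply(disp$vectors, 2, sd) / sqrt(disp$count)
}

shift_estimate <- function(shift, err, n_pairs, n_iter, converged, valid) {
  structure(list(shift = shift, err = err, n_pairs = as.integer(n_pairs),
                 n_iter = as.integer(n_iter), converged = converged,
                 valid = valid),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> shift = (%s) nm, err = (%s) nm, %d pairs, %d iter, %s\n",
              paste(signif(x$shift, 4), collapse = ", "),
              paste(signif(x$err, 3), collapse = ", "),
              x$n_pairs, x$n_iter,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}
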