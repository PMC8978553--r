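#' Split a localization table into two halves by frame blocks
#'
#' Fourier ring correlation needs two statistically independent
#' reconstructions of the same structure. Frames are grouped into
#' consecutive blocks (default 50 frames) and whole blocks are randomly
#' assigned half/half; splitting by blocks rather than per-localization
#' coin flips keeps most of a fluorophore's blinking run on one side,
#' blunting the spurious correlation that repeated localizations of the
#' same emitter would otherwise inject across halves.
#'
#' @param table a [loc_table()] with at least 2 localizations.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param block_frames frames per block; must be smaller than the frame
#'   span (a one-block split is rejected).
#' @return list of two [loc_table()]s forming a disjoint partition of
#'   `table`.
#' @export
split_halves <- function(table, seed = 1, block_frames = 50) {
  validate_loc_table(table)
  stopifnot(nrow(table) >= 2, block_frames >= 1)
  F_max <- max(table$frame)
  block <- (table$frame - 1) %/% block_frames + 1
  n_blocks <- max(block)
  if (n_blocks < 2)
    stop("block_frames = ", block_frames, " yields a single block over ",
         F_max, " frames; choose a smaller block size")
  set.seed(seed)
  perm <- sample.int(n_blocks)
  first <- perm[seq_len(n_blocks %/% 2)]
  sel <- block %in% first
  h1 <- table[sel, , drop = FALSE]
  h2 <- table[!sel, , drop = FALSE]
  class(h1) <- class(h2) <- c("loc_table", "data.frame")
  list(h1, h2)
}

#' Render a localization table as a 2D count histogram
#'
#' The standard SMLM reconstruction: a 2D histogram of the (x, y)
#' positions on a square pixel grid. For 3D tables z is ignored (the ring
#' correlation is evaluated in-plane).
#'
#' @param table a [loc_table()].
#' @param pixel_nm pixel size in nm (> 0).
#' @param extent list with `xlim` and `ylim` (nm); pixels cover
#'   `[lim[1], lim[1] + n * pixel_nm)`.
#' @return integer matrix of counts (rows = x bins, cols = y bins).
#' @export
render_histogram <- function(table, pixel_nm, extent) {
  stopifnot(pixel_nm > 0)
  nx <- max(1L, ceiling(diff(extent$xlim) / pixel_nm))
  ny <- max(1L, ceiling(diff(extent$ylim) / pixel_nm))
  img <- matrix(0L, nx, ny)
  if (nrow(table) == 0) return(img)
  ix <- floor((table$x - extent$xlim[1]) / pixel_nm) + 1
  iy <- floor((table$y - extent$ylim[1]) / pixel_nm) + 1
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  counts <- tabulate((iy[keep] - 1L) * nx + ix[keep], nbins = nx * ny)
  matrix(counts, nx, ny)
}

#' Fourier ring correlation curve of two images
#'
#' Correlation of the two images' Fourier transforms over rings of equal
#' spatial frequency: `FRC(q) = Re sum(F_A conj(F_B)) / sqrt(sum|F_A|^2 *
#' sum|F_B|^2)`, ring width one frequency sample, lightly smoothed by a
#' 3-ring moving average.
#'
#' @param imgA,imgB square count images of identical shape.
#' @param pixel_nm pixel size in nm (sets the frequency axis).
#' @return list with `freq` (1/nm per ring), `frc` (smoothed curve) and
#'   `frc_raw`.
#' @export
frc_curve <- function(imgA, imgB, pixel_nm = 1) {
  if (!all(dim(imgA) == dim(imgB))) stop("image shape mismatch")
  n <- nrow(imgA)
  if (ncol(imgA) != n) stop("images must be square")
  FA <- fft(imgA); FB <- fft(imgB)
  # ring index from unshifted FFT frequencies
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  ring <- round(sqrt(outer(f^2, f^2, `+`)))
  nr <- n %/% 2
  idx <- which(ring <= nr - 1)
  rk <- ring[idx] + 1L
  num <- vapply(split(Re(FA[idx] * Conj(FB[idx])), rk), sum, 0)
  dA <- vapply(split(abs(FA[idx])^2, rk), sum, 0)
  dB <- vapply(split(abs(FB[idx])^2, rk), sum, 0)
  raw <- num / sqrt(dA * dB)
  raw[!is.finite(raw)] <- 0
  sm <- as.numeric(stats::filter(raw, rep(1 / 3, 3)))
  sm[is.na(sm)] <- raw[is.na(sm)]
  list(freq = (seq_along(raw) - 1) / (n * pixel_nm), frc = sm,
       frc_raw = raw)
}

#' FRC resolution of a localization table
#'
#' Repeats split -> render -> ring correlation with distinct sub-seeds and
#' reports the resolution per replicate as the inverse of the first
#' spatial frequency at which the smoothed FRC falls below the threshold
#' (1/7 by default, the standard fixed-threshold criterion). The crossing
#' frequency is linearly interpolated between rings.
#'
#' @param table a [loc_table()]; a warning is issued below 1000
#'   localizations.
#' @param pixel_nm reconstruction pixel size, nm; images are zero-padded
#'   to a square power-of-two side.
#' @param n_replicates number of random splits.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param threshold FRC threshold.
#' @param block_frames frames per split block (see [split_halves()]).
#' @return object of class `"frc_result"`: list with `resolution` (mean
#'   over replicates, nm; `NA` if no crossing), `resolution_sd`,
#'   `per_replicate`, `freq`, `correlation` (last replicate's smoothed
#'   curve), `threshold`, `n_replicates`.
#' @export
frc_resolution <- function(table, pixel_nm = 5, n_replicates = 20,
                           seed = 1, threshold = 1 / 7,
                           block_frames = 50) {
  validate_loc_table(table)
  if (nrow(table) < 1000)
    warning("fewer than 1000 localizations; FRC resolution will be noisy")
  pad <- function(npix) 2^ceiling(log2(npix))
  ext0 <- list(xlim = range(table$x), ylim = range(table$y))
  npix <- max(ceiling(diff(ext0$xlim) / pixel_nm),
              ceiling(diff(ext0$ylim) / pixel_nm), 2)
  n <- pad(npix)
  extent <- list(xlim = c(ext0$xlim[1], ext0$xlim[1] + n * pixel_nm),
                 ylim = c(ext0$ylim[1], ext0$ylim[1] + n * pixel_nm))
  res <- rep(NA_real_, n_replicates)
  curve <- NULL
  for (r in seq_len(n_replicates)) {
    halves <- split_halves(table, seed = seed + r,
                           block_frames = block_frames)
    imgA <- render_histogram(halves[[1]], pixel_nm, extent)
    imgB <- render_histogram(halves[[2]], pixel_nm, extent)
    curve <- frc_curve(imgA, imgB, pixel_nm)
    res[r] <- .frc_crossing(curve$freq, curve$frc, threshold)
  }
  structure(list(resolution = if (all(is.na(res))) NA_real_ else
                   mean(res, na.rm = TRUE),
                 resolution_sd = stats::sd(res, na.rm = TRUE),
                 per_replicate = res,
                 freq = curve$freq, correlation = curve$frc,
                 threshold = threshold,
                 n_replicates = as.integer(n_replicates)),
            class = "frc_result")
}

# first downward crossing of the threshold, linearly interpolated;
# NA when the curve never crosses below the Nyquist frequency
.frc_crossing <- function(freq, frc, threshold) {
  below <- which(frc < threshold & seq_along(frc) > 1)
  if (length(below) == 0) return(NA_real_)
  k <- below[1]
  f0 <- freq[k - 1]; f1 <- freq[k]
  y0 <- frc[k - 1]; y1 <- frc[k]
  fc <- if (y0 == y1) f1 else f0 + (y0 - threshold) * (f1 - f0) / (y0 - y1)
  1 / fc
}

#' @export
print.frc_result <- function(x, ...) {
  cat(sprintf("<frc_result> resolution = %.1f +/- %.1f nm (threshold %.3g, %d replicates)\n",
              x$resolution, x$resolution_sd, x$threshold, x$n_replicates))
  invisible(x)
}

#' Plot an FRC curve with its threshold
#'
#' @param x an `"frc_result"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.frc_result <- function(x, ...) {
  graphics::plot(x$freq, x$correlation, type = "l",
                 xlab = "spatial frequency [1/nm]", ylab = "FRC", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
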