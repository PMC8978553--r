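#' Extract in-window pairwise displacements between two point sets
#'
#' Computes every displacement `b - a` (for `a` in `A`, `b` in `B`) that
#' falls inside a closed ball of the given radius centered on `center` —
#' the raw material of the mean-shift estimator. Implemented with a
#' cell-list (grid hash) query so the cost is near-linear in the number of
#' points at fixed local density, rather than quadratic.
#'
#' For 3D data with anisotropic precision, `scale` rescales each axis
#' before the query (e.g. `c(1, 1, 0.5)` to admit axial separations twice
#' the lateral ones), turning the spherical window into an axis-aligned
#' ellipsoid. Stored displacements are always in the original coordinates.
#'
#' @param A,B numeric matrices (rows = points, columns = axes) or
#'   [loc_table()]s of the same dimension; both non-empty.
#' @param center numeric vector, the window center (a shift guess), nm.
#' @param radius window radius in nm (> 0); the boundary is included.
#' @param scale optional per-axis scale factors applied before the query.
#' @return An object of class `"displacement_set"`: a list with `vectors`
#'   (n x d matrix of displacements), `count`, `center`, `radius`.
#' @examples
#' A <- rbind(c(0, 0), c(1000, 0))
#' cross_pairs(A, sweep(A, 2, c(-25, -25)), center = c(0, 0), radius = 150)
#' @export
cross_pairs <- function(A, B, center, radius, scale = NULL) {
  A <- loc_coords(A); B <- loc_coords(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty")
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets")
  d <- ncol(A)
  stopifnot(length(center) == d, is.finite(radius), radius > 0)
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  center <- as.double(center)
  if (!is.null(scale)) {
    stopifnot(length(scale) == d, all(scale > 0))
    As <- sweep(A, 2, scale, `*`); Bs <- sweep(B, 2, scale, `*`)
    v <- .pairs_query(As, Bs, center * scale, radius)
    v <- sweep(v, 2, scale, `/`)
  } else {
    v <- .pairs_query(A, B, center, radius)
  }
  displacement_set(v, center, radius)
}

# dispatch to the C++ cell list; fall back to brute force when the grid key
# space would overflow (pathological extent/radius ratios)
.pairs_query <- function(A, B, center, radius) {
  d <- ncol(A)
  rng <- apply(rbind(A, sweep(B, 2, center)), 2, function(u) diff(range(u)))
  if (prod(rng / radius + 3) < 2^61) {
    cross_pairs_cpp(A, B, center, radius)
  } else {
    .brute_pairs_matrix(A, B, center, radius)
  }
}

.brute_pairs_matrix <- function(A, B, center, radius) {
  d <- ncol(A)
  v <- matrix(0, nrow = nrow(A) * nrow(B), ncol = d)
  for (k in seq_len(d))
    v[, k] <- rep(B[, k], each = nrow(A)) - rep(A[, k], times = nrow(B))
  dist2 <- rowSums(sweep(v, 2, center)^2)
  v[dist2 <= radius^2, , drop = FALSE]
}

#' @rdname cross_pairs
#' @details `brute_force_pairs()` enumerates all `|A| * |B|` pairs with the
#'   same inclusion rule; it is the reference oracle for `cross_pairs()` and
#'   only suitable for small inputs.
#' @export
brute_force_pairs <- function(A, B, center, radius) {
  A <- loc_coords(A); B <- loc_coords(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be non-empty")
  if (ncol(A) != ncol(B)) stop("dimension mismatch between point sets")
  stopifnot(length(center) == ncol(A), radius > 0)
  displacement_set(.brute_pairs_matrix(A, B, as.double(center), radius),
                   as.double(center), radius)
}

displacement_set <- function(vectors, center, radius) {
  structure(list(vectors = vectors, count = nrow(vectors),
                 center = center, radius = radius),
            class = "displacement_set")
}

#' @export
print.displacement_set <- function(x, ...) {
  cat(sprintf("<displacement_set> %d vectors in |v - (%s)| <= %g nm\n",
              x$count, paste(signif(x$center, 4), collapse = ", "),
              x$radius))
  invisible(x)
}
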