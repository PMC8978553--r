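# shared test helpers: random point sets and multiset comparison

random_points <- function(n, d, lim = 1000) {
  matrix(runif(n * d, 0, lim), n, d)
}

# canonical row order for comparing displacement sets as multisets
sort_rows <- function(m) {
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

expect_same_multiset <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) > 0)
    expect_equal(sort_rows(a), sort_rows(b), tolerance = tol,
                 ignore_attr = TRUE)
}

# wrap a bare displacement matrix for estimate_error tests
displacement_set_for_test <- function(vectors, center, radius) {
  msdrift:::displacement_set(vectors, center, radius)
}

# two well-separated molecules, one localization each, B translated
two_molecule_pair <- function(shift = c(25, 25)) {
  A <- rbind(c(0, 0), c(1000, 0))
  list(A = A, B = sweep(A, 2, -shift))
}
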