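# Internal helpers shared across modules.

# Row-wise medians of a numeric matrix.
# One radix sort keyed on (row, value) sorts all rows at once, which is far
# faster inside the permutation loop than per-row apply().
row_medians <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = length(m))
  n <- ncol(m)
  if (n == 0L) stop("cannot take the median of zero pair matrices")
  if (n == 1L) return(m[, 1L])
  nr <- nrow(m)
  o <- order(rep.int(seq_len(nr), n), m, method = "radix")
  s <- matrix(m[o], nr, n, byrow = TRUE)
  half <- n %/% 2L
  if (n %% 2L == 1L) s[, half + 1L]
  else (s[, half] + s[, half + 1L]) / 2
}

# Upper-triangle (i < j) values of a square matrix in row-major pair order
# (1,2), (1,3), ..., (1,R), (2,3), ...
upper_tri_values <- function(m) {
  t(m)[lower.tri(m)]
}

# Index pairs (i, j), i < j, in the same row-major order as upper_tri_values().
upper_tri_pairs <- function(r) {
  idx <- which(lower.tri(matrix(0, r, r)), arr.ind = TRUE)
  data.frame(i = idx[, "col"], j = idx[, "row"])[order(idx[, "col"], idx[, "row"]), ,
                                                 drop = FALSE]
}

# Flatten / reconstruct symmetric matrices through the upper triangle
# including the diagonal (column-major; order is internal only).
flatten_sym <- function(m) {
  m[upper.tri(m, diag = TRUE)]
}

unflatten_sym <- function(v, r, labels = NULL) {
  m <- matrix(0, r, r)
  m[upper.tri(m, diag = TRUE)] <- v
  lo <- lower.tri(m)
  m[lo] <- t(m)[lo]
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Standardize columns to mean 0, sample (n-1) standard deviation 1.
standardize_columns <- function(x, context = "series") {
  x <- as.matrix(x)
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  bad <- which(s < 1e-12)
  if (length(bad)) {
    stop(sprintf("zero-variance column(s) in %s: %s", context,
                 paste(colnames(x)[bad] %||% bad, collapse = ", ")))
  }
  sweep(x, 2L, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a seeded RNG, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_region_labels <- function(r) sprintf("ROI_%03d", seq_len(r))

stopifnot_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
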