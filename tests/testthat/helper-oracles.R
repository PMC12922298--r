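# Independent oracles and small fixture builders used across tests.

# Naive per-entry Pearson ISFC: double loop over region pairs, then
# symmetrize by averaging with the transpose.
naive_pair_isfc <- function(a, b) {
  r <- ncol(a)
  raw <- matrix(NA_real_, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    raw[i, j] <- stats::cor(a[, i], b[, j])
  }
  (raw + t(raw)) / 2
}

# Normal-equations least squares: residuals of y on design X.
naive_ols_residuals <- function(y, x) {
  beta <- solve(t(x) %*% x, t(x) %*% y)
  y - x %*% beta
}

# A null (no group effect) configuration: equal weights in both groups.
null_config <- function(seed, n_regions = 15L, n_timepoints = 200L,
                        group_sizes = c(10L, 10L), weight = 0.7, ...) {
  w <- rep(weight, n_regions)
  synthetic_config(n_regions = n_regions, n_timepoints = n_timepoints,
                   group_sizes = group_sizes,
                   weights = list(w, w), seed = seed, ...)
}

# Clean every subject of a dataset with its own confounds.
clean_all <- function(dataset) {
  lapply(dataset$subjects, function(s)
    regress_confounds(s$data, dataset$confounds[[s$subject_id]],
                      subject_id = s$subject_id, group = s$group))
}

# Random sparse signed mask for replication tests: each strict upper
# triangle cell is nonzero with probability `density`, sign balanced.
random_mask <- function(r, density, alpha = 0.05) {
  m <- matrix(0, r, r)
  ut <- which(upper.tri(m))
  on_cells <- ut[stats::runif(length(ut)) < density]
  m[on_cells] <- sample(c(-1, 1), length(on_cells), replace = TRUE)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  significance_mask(m, alpha = alpha)
}

# Mask with prescribed (i, j, sign) pairs.
mask_from_pairs <- function(r, pairs, alpha = 0.05) {
  m <- matrix(0, r, r)
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  significance_mask(m, alpha = alpha)
}
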