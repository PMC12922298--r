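#' Symmetrized pairwise ISFC matrix for one subject pair
#'
#' The raw entry (i, j) is the Pearson correlation between subject a's
#' region-i time series and subject b's region-j time series; because only
#' the stimulus is shared between two different brains, these cross-subject
#' correlations isolate stimulus-locked coupling. Connection direction is
#' not analyzed, so the raw matrix is symmetrized by averaging with its
#' transpose. The diagonal holds the symmetrized inter-subject correlation
#' (ISC) of each region.
#'
#' @param series_a,series_b `cleaned_series` objects or T x R matrices with
#'   matching dimensions and region order.
#' @return Symmetric R x R matrix with entries in `[-1, 1]`.
#' @export
subject_pair_isfc <- function(series_a, series_b) {
  a <- series_data(series_a)
  b <- series_data(series_b)
  if (!identical(dim(a), dim(b)))
    stop("subject series must share T and R")
  a <- standardize_columns(a, context = "series_a")
  b <- standardize_columns(b, context = "series_b")
  raw <- crossprod(a, b) / (nrow(a) - 1L)
  out <- (raw + t(raw)) / 2
  dimnames(out) <- list(colnames(series_data(series_a)),
                        colnames(series_data(series_a)))
  out
}

series_data <- function(x) {
  if (inherits(x, "cleaned_series")) x$data else as.matrix(x)
}

#' Pairwise ISFC tensor for one group of subjects
#'
#' Computes the symmetrized ISFC matrix for every unordered pair of
#' subjects: n(n-1)/2 matrices for n subjects. Correlations use the
#' standardized cross-product identity (dot product of standardized columns
#' divided by T - 1), which equals the naive per-entry Pearson computation.
#'
#' @param subjects List of `cleaned_series` objects (or T x R matrices)
#'   with identical dimensions and region order.
#' @return Object of class `isfc_pair_tensor`: list with `pair_index`
#'   (data frame of subject id pairs), `matrices` (R x R x n_pairs array),
#'   `region_labels`.
#' @export
group_pairwise_isfc <- function(subjects) {
  n <- length(subjects)
  if (n < 2L) stop("need at least 2 subjects")
  mats <- lapply(subjects, series_data)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share T and R")
  r <- dims[2, 1]
  labels <- colnames(mats[[1L]]) %||% default_region_labels(r)
  ids <- vapply(seq_len(n), function(k) {
    s <- subjects[[k]]
    if (inherits(s, "cleaned_series") && !is.na(s$subject_id)) s$subject_id
    else sprintf("sub-%02d", k)
  }, character(1))

  z <- lapply(mats, standardize_columns)
  tt <- dims[1, 1]
  n_pairs <- n * (n - 1L) / 2L
  arr <- array(NA_real_, c(r, r, n_pairs),
               dimnames = list(labels, labels, NULL))
  pair_a <- pair_b <- integer(n_pairs)
  k <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      k <- k + 1L
      raw <- crossprod(z[[a]], z[[b]]) / (tt - 1L)
      arr[, , k] <- (raw + t(raw)) / 2
      pair_a[k] <- a; pair_b[k] <- b
    }
  }
  structure(
    list(pair_index = data.frame(a = ids[pair_a], b = ids[pair_b]),
         matrices = arr,
         region_labels = labels),
    class = "isfc_pair_tensor")
}

#' @export
print.isfc_pair_tensor <- function(x, ...) {
  cat(sprintf("Pairwise ISFC tensor: %d subject pairs, %d regions\n",
              dim(x$matrices)[3], dim(x$matrices)[1]))
  invisible(x)
}

#' Median ISFC summary for a group
#'
#' The group summary statistic is the entrywise median over all
#' subject-pair matrices (midpoint of the two central order statistics for
#' even pair counts). No Fisher z-transform is applied before the median:
#' the median is equivariant under monotone transforms, so the median of
#' correlations and the back-transformed median of z-values coincide.
#'
#' @param tensor An `isfc_pair_tensor` from [group_pairwise_isfc()].
#' @param group Group label recorded in the summary.
#' @return Object of class `isfc_group_summary`: `median_matrix` (R x R),
#'   `unique_values` (the R(R-1)/2 strict-upper-triangle values in row-major
#'   pair order), `group`, `n_subjects`, `region_labels`.
#' @export
median_isfc <- function(tensor, group = NA_character_) {
  stopifnot(inherits(tensor, "isfc_pair_tensor"))
  n_pairs <- dim(tensor$matrices)[3]
  if (n_pairs < 1L) stop("empty pair tensor")
  r <- dim(tensor$matrices)[1]
  med <- matrix(row_medians(matrix(tensor$matrices, r * r, n_pairs)), r, r)
  dimnames(med) <- list(tensor$region_labels, tensor$region_labels)
  n_subjects <- length(unique(c(tensor$pair_index$a, tensor$pair_index$b)))
  structure(
    list(median_matrix = med,
         unique_values = upper_tri_values(med),
         group = group,
         n_subjects = n_subjects,
         region_labels = tensor$region_labels),
    class = "isfc_group_summary")
}

#' @export
print.isfc_group_summary <- function(x, ...) {
  cat(sprintf("Group ISFC summary (%s): %d subjects, %d regions, %d unique pairs\n",
              x$group, x$n_subjects, length(x$region_labels),
              length(x$unique_values)))
  cat(sprintf("  median ISFC range: [%.4f, %.4f]\n",
              min(x$unique_values), max(x$unique_values)))
  invisible(x)
}

#' Number of unique region pairs
#'
#' For an R-region atlas the symmetrized ISFC matrix has R(R-1)/2 unique
#' off-diagonal pairs; a 273-region atlas yields 37,128.
#'
#' @param n_regions Number of regions (>= 2).
#' @return Integer pair count.
#' @export
unique_pair_count <- function(n_regions) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 2)
    stop("'n_regions' must be a single integer >= 2")
  n <- as.integer(n_regions)
  (n * (n - 1L)) %/% 2L
}

#' Entrywise group difference of median ISFC
#'
#' First-group median minus second-group median (neurotypical minus autism
#' in the pipeline defaults); positive entries mark inter-subject
#' hypoconnectivity in the second group.
#'
#' @param summary_a,summary_b `isfc_group_summary` objects over the same
#'   regions in the same order.
#' @return Symmetric R x R difference matrix.
#' @export
isfc_difference <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "isfc_group_summary"),
            inherits(summary_b, "isfc_group_summary"))
  if (!identical(summary_a$region_labels, summary_b$region_labels))
    stop("region labels differ between the two summaries")
  summary_a$median_matrix - summary_b$median_matrix
}
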