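#' Signed overlap of two significance masks
#'
#' Entrywise sum of the discovery and replication masks: +2 marks pairs
#' significantly positive in both datasets, -2 significantly negative in
#' both; +1/-1/0 are non-replicated. Region label order must match exactly
#' (no silent reordering).
#'
#' @param mask_discovery,mask_replication `isfc_mask` objects over the same
#'   regions in the same order.
#' @return R x R integer matrix over \{-2, -1, 0, +1, +2\}.
#' @export
signed_overlap <- function(mask_discovery, mask_replication) {
  stopifnot(inherits(mask_discovery, "isfc_mask"),
            inherits(mask_replication, "isfc_mask"))
  if (!identical(mask_discovery$region_labels, mask_replication$region_labels))
    stop("region label order differs between the two masks; no silent reordering")
  mask_discovery$values + mask_replication$values
}

#' Cross-dataset replication rate
#'
#' The proportion of significant pairwise group differences in the
#' discovery dataset that are also significant, with the same sign and the
#' same pair of region indices, in the replication dataset — i.e. the
#' number of upper-triangle overlap cells at +2 or -2 divided by the number
#' of significant upper-triangle discovery pairs. Diagonal excluded
#' throughout.
#'
#' @inheritParams signed_overlap
#' @return A number in `[0, 1]`.
#' @export
replication_rate <- function(mask_discovery, mask_replication) {
  ov <- signed_overlap(mask_discovery, mask_replication)
  rate_from_matrices(mask_discovery$values, mask_replication$values)
}

# Rate on raw -1/0/1 matrices; used in the shuffle loop where the label
# bookkeeping of the mask objects is irrelevant.
rate_from_matrices <- function(md, mr) {
  d_ut <- upper_tri_values(md)
  n_disc <- sum(d_ut != 0)
  if (n_disc == 0L)
    stop("discovery mask has no significant pairs; replication rate undefined")
  n_rep <- sum(abs(upper_tri_values(md + mr)) == 2)
  n_rep / n_disc
}

#' ROI-shuffle permutation test of the replication rate
#'
#' Builds a null distribution for the replication rate by randomly
#' shuffling the region order of the replication mask (rows and columns
#' permuted identically, discovery mask fixed) `n_shuffles` times and
#' recomputing the rate. The p-value is
#' `(1 + #\{null rate >= observed\}) / (1 + n_shuffles)`.
#'
#' @inheritParams signed_overlap
#' @param n_shuffles Number of random region permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed_rate`, `null_rates`,
#'   `n_shuffles`, `seed`.
#' @export
roi_shuffle_pvalue <- function(mask_discovery, mask_replication,
                               n_shuffles = 5000L, seed = NULL) {
  if (n_shuffles < 100L) stop("'n_shuffles' must be at least 100")
  ov <- signed_overlap(mask_discovery, mask_replication)  # validates labels
  md <- mask_discovery$values
  mr <- mask_replication$values
  observed <- rate_from_matrices(md, mr)
  r <- ncol(md)
  null_rates <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      p <- sample.int(r)
      rate_from_matrices(md, mr[p, p])
    }, numeric(1))
  })
  p <- (1 + sum(null_rates >= observed)) / (1 + n_shuffles)
  list(p_value = p, observed_rate = observed, null_rates = null_rates,
       n_shuffles = as.integer(n_shuffles), seed = seed)
}

#' Cross-dataset correlation of ISFC group-difference matrices
#'
#' Pearson correlation between the two datasets' group-difference matrices
#' over the R(R-1)/2 unique upper-triangle values, with a two-sided
#' permutation p-value from the same ROI-shuffle null (one random region
#' permutation applied to the rows and columns of the second matrix per
#' shuffle).
#'
#' @param diff_discovery,diff_replication Symmetric R x R group-difference
#'   matrices with matching region order.
#' @param n_shuffles Number of region permutations.
#' @param seed Integer seed.
#' @return List with `pearson_r`, `p_value`, `null_r`, `n_shuffles`.
#' @export
cross_dataset_correlation <- function(diff_discovery, diff_replication,
                                      n_shuffles = 5000L, seed = NULL) {
  d1 <- as.matrix(diff_discovery)
  d2 <- as.matrix(diff_replication)
  if (!identical(dim(d1), dim(d2))) stop("matrices must share dimensions")
  l1 <- colnames(d1); l2 <- colnames(d2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("region label order differs between the two matrices")
  v1 <- upper_tri_values(d1)
  if (stats::sd(v1) == 0 || stats::sd(upper_tri_values(d2)) == 0)
    stop("zero-variance upper triangle; correlation undefined")
  observed <- stats::cor(v1, upper_tri_values(d2))
  r <- ncol(d1)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      p <- sample.int(r)
      stats::cor(v1, upper_tri_values(d2[p, p]))
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_r) >= abs(observed))) / (1 + n_shuffles)
  list(pearson_r = observed, p_value = p, null_r = null_r,
       n_shuffles = as.integer(n_shuffles), seed = seed)
}

#' Full cross-dataset replication summary
#'
#' Convenience wrapper combining [signed_overlap()], [replication_rate()],
#' [roi_shuffle_pvalue()] and (when difference matrices are supplied)
#' [cross_dataset_correlation()] into one result object, including the
#' replicated-pair table with the mean group difference across datasets.
#'
#' @inheritParams roi_shuffle_pvalue
#' @param diff_discovery,diff_replication Optional group-difference
#'   matrices for the replicated-pair table and cross-dataset correlation.
#' @return Object of class `isfc_replication_result`.
#' @export
replication_result <- function(mask_discovery, mask_replication,
                               diff_discovery = NULL, diff_replication = NULL,
                               n_shuffles = 5000L, seed = NULL) {
  overlap <- signed_overlap(mask_discovery, mask_replication)
  shuffle <- roi_shuffle_pvalue(mask_discovery, mask_replication,
                                n_shuffles = n_shuffles, seed = seed)
  pairs <- upper_tri_pairs(ncol(overlap))
  ut <- upper_tri_values(overlap)
  rep_idx <- which(abs(ut) == 2)
  labels <- mask_discovery$region_labels
  replicated <- data.frame(
    region_i = labels[pairs$i[rep_idx]],
    region_j = labels[pairs$j[rep_idx]],
    sign = as.integer(sign(ut[rep_idx])))
  if (!is.null(diff_discovery) && !is.null(diff_replication)) {
    mean_diff <- (upper_tri_values(as.matrix(diff_discovery)) +
                    upper_tri_values(as.matrix(diff_replication))) / 2
    replicated$mean_difference <- mean_diff[rep_idx]
    corr <- cross_dataset_correlation(diff_discovery, diff_replication,
                                      n_shuffles = n_shuffles, seed = seed)
  } else corr <- NULL

  structure(
    list(overlap = overlap, replicated_pairs = replicated,
         rate = shuffle$observed_rate, null_rates = shuffle$null_rates,
         p_value = shuffle$p_value, cross_correlation = corr,
         n_shuffles = as.integer(n_shuffles), seed = seed),
    class = "isfc_replication_result")
}

#' @export
print.isfc_replication_result <- function(x, ...) {
  cat(sprintf("Replication of ISFC group differences: rate %.3f (p = %.4g, %d ROI shuffles)\n",
              x$rate, x$p_value, x$n_shuffles))
  cat(sprintf("  replicated pairs: %d\n", nrow(x$replicated_pairs)))
  if (!is.null(x$cross_correlation))
    cat(sprintf("  cross-dataset Pearson r = %.3f (p = %.4g)\n",
                x$cross_correlation$pearson_r, x$cross_correlation$p_value))
  invisible(x)
}
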