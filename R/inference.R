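#' Pooled pair tensor over both groups
#'
#' Precomputes the symmetrized ISFC matrix for every unordered pair of the
#' pooled subject set, so that subject-wise label permutations only need to
#' re-select within-group pair columns, never recompute correlations.
#' Restricting to within-group pairs of the true labels reproduces each
#' group's [group_pairwise_isfc()] tensor exactly.
#'
#' @param subjects List of `cleaned_series` objects (or T x R matrices)
#'   for all subjects of both groups.
#' @param labels Group label per subject; defaults to the `group` field of
#'   each `cleaned_series`.
#' @param group_order Character vector of length 2; the first label is the
#'   minuend of all difference statistics. Defaults to the sorted unique
#'   labels.
#' @return Object of class `isfc_pooled_tensor`.
#' @export
pooled_pair_tensor <- function(subjects, labels = NULL, group_order = NULL) {
  if (is.null(labels))
    labels <- vapply(subjects, function(s) {
      if (inherits(s, "cleaned_series")) s$group else NA_character_
    }, character(1))
  labels <- as.character(labels)
  if (length(labels) != length(subjects) || anyNA(labels))
    stop("need one group label per subject")
  if (is.null(group_order)) group_order <- sort(unique(labels))
  if (length(group_order) != 2L || !setequal(group_order, unique(labels)))
    stop("exactly two groups required")
  if (any(table(factor(labels, group_order)) < 2L))
    stop("each group needs at least 2 subjects")

  tensor <- group_pairwise_isfc(subjects)
  r <- length(tensor$region_labels)
  n <- length(subjects)
  n_pairs <- dim(tensor$matrices)[3]
  n_cells <- r * (r + 1L) / 2L
  values <- matrix(NA_real_, n_cells, n_pairs)
  for (k in seq_len(n_pairs)) values[, k] <- flatten_sym(tensor$matrices[, , k])

  pair_i <- pair_j <- integer(n_pairs)
  k <- 0L
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    k <- k + 1L; pair_i[k] <- a; pair_j[k] <- b
  }
  ids <- vapply(seq_len(n), function(k) {
    s <- subjects[[k]]
    if (inherits(s, "cleaned_series") && !is.na(s$subject_id)) s$subject_id
    else sprintf("sub-%02d", k)
  }, character(1))

  structure(
    list(values = values, pair_i = pair_i, pair_j = pair_j,
         subject_ids = ids, labels = labels, group_order = group_order,
         region_labels = tensor$region_labels, n_regions = r,
         pair_index = tensor$pair_index),
    class = "isfc_pooled_tensor")
}

#' @export
print.isfc_pooled_tensor <- function(x, ...) {
  cat(sprintf("Pooled pair tensor: %d subjects (%s), %d pairs, %d regions (~%.1f MB)\n",
              length(x$labels),
              paste(sprintf("%s %d", x$group_order,
                            table(factor(x$labels, x$group_order))), collapse = ", "),
              ncol(x$values), x$n_regions,
              8 * length(x$values) / 2^20))
  invisible(x)
}

# Core subject-wise permutation engine over a flat cell x pair value matrix.
# Returns the observed group-difference statistic per cell plus the null
# matrix (cells x permutations). Enumerates all label assignments when the
# number of distinct shuffles does not exceed n_permutations.
permutation_engine <- function(values, pair_i, pair_j, labels, group_order,
                               n_permutations, seed = NULL) {
  values <- as.matrix(values)
  n <- length(labels)
  is1_true <- labels == group_order[1L]
  n1 <- sum(is1_true)
  stat <- function(is1) {
    sel1 <- is1[pair_i] & is1[pair_j]
    sel2 <- !is1[pair_i] & !is1[pair_j]
    row_medians(values[, sel1, drop = FALSE]) -
      row_medians(values[, sel2, drop = FALSE])
  }
  observed <- stat(is1_true)

  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_permutations
  if (exhaustive) {
    warning(sprintf(paste0("only %d distinct label shuffles exist; ",
                           "enumerating all of them instead of %d random draws"),
                    n_distinct, n_permutations), call. = FALSE)
    sets <- utils::combn(n, n1)
    nulls <- matrix(NA_real_, length(observed), ncol(sets))
    for (k in seq_len(ncol(sets))) {
      is1 <- rep(FALSE, n); is1[sets[, k]] <- TRUE
      nulls[, k] <- stat(is1)
    }
  } else {
    nulls <- with_seed(seed, {
      out <- matrix(NA_real_, length(observed), n_permutations)
      for (k in seq_len(n_permutations)) {
        is1 <- rep(FALSE, n); is1[sample.int(n, n1)] <- TRUE
        out[, k] <- stat(is1)
      }
      out
    })
  }
  list(observed = observed, nulls = nulls,
       n_permutations = ncol(nulls), exhaustive = exhaustive)
}

#' Subject-wise permutation test of median ISFC group differences
#'
#' The observed statistic for every region pair is the entrywise difference
#' of within-group median ISFC (first group of `pool$group_order` minus the
#' second). Each permutation shuffles whole subjects' group labels
#' (preserving group sizes and within-subject temporal structure) and
#' recomputes the same statistic from the precomputed pooled pair tensor.
#' A pair is significant at level alpha when the observed difference
#' exceeds the upper `1 - alpha/2` per-pair null percentile or falls below
#' the `alpha/2` percentile (two-sided; for alpha = .05, the 97.5th/2.5th
#' percentiles). Per-pair p-values use the add-one convention
#' `(1 + #\{|null| >= |observed|\}) / (1 + n_permutations)` and are never 0.
#' No multiple-comparison correction is applied.
#'
#' When the number of distinct label assignments is at most
#' `n_permutations`, all of them are enumerated (with a warning) instead of
#' sampling with replacement.
#'
#' @param pool An [pooled_pair_tensor()].
#' @param n_permutations Number of label shuffles (default 5000).
#' @param alphas Two-sided significance levels for the signed masks.
#' @param seed Integer seed for the label shuffles.
#' @return Object of class `isfc_permutation_result` with `observed_diff`,
#'   `null_quantiles`, `p_values`, `masks` (one `isfc_mask` per alpha),
#'   `n_permutations`, `exhaustive`, `seed`, `group_order`.
#' @export
subject_wise_permutation_test <- function(pool, n_permutations = 5000L,
                                          alphas = c(0.05, 0.01),
                                          seed = NULL) {
  stopifnot(inherits(pool, "isfc_pooled_tensor"))
  if (n_permutations < 100L) stop("'n_permutations' must be at least 100")
  eng <- permutation_engine(pool$values, pool$pair_i, pool$pair_j,
                            pool$labels, pool$group_order,
                            n_permutations, seed)
  r <- pool$n_regions
  labels <- pool$region_labels
  observed <- unflatten_sym(eng$observed, r, labels)

  probs <- sort(unique(c(alphas / 2, 1 - alphas / 2, 0.025, 0.975, 0.005, 0.995)))
  qs <- apply(eng$nulls, 1L, stats::quantile, probs = probs, names = FALSE)
  null_quantiles <- lapply(seq_along(probs), function(k)
    unflatten_sym(qs[k, ], r, labels))
  names(null_quantiles) <- sprintf("q%s", format(probs * 100, trim = TRUE))

  p_flat <- (1 + rowSums(abs(eng$nulls) >= abs(eng$observed))) /
    (1 + eng$n_permutations)
  p_values <- unflatten_sym(p_flat, r, labels)

  masks <- lapply(alphas, function(alpha) {
    lo <- qs[match(alpha / 2, probs), ]
    hi <- qs[match(1 - alpha / 2, probs), ]
    m_flat <- as.numeric(eng$observed > hi) - as.numeric(eng$observed < lo)
    significance_mask(unflatten_sym(m_flat, r, labels), alpha)
  })
  names(masks) <- format(alphas, trim = TRUE)

  structure(
    list(observed_diff = observed, null_quantiles = null_quantiles,
         p_values = p_values, masks = masks,
         n_permutations = eng$n_permutations, exhaustive = eng$exhaustive,
         seed = seed, group_order = pool$group_order,
         group_sizes = table(factor(pool$labels, pool$group_order))),
    class = "isfc_permutation_result")
}

#' Signed significance mask
#'
#' @param values R x R matrix over \{-1, 0, +1\}: +1 where the first group's
#'   median ISFC significantly exceeds the second group's, -1 for the
#'   reverse. The diagonal is always 0 (ISC differences are excluded from
#'   pair-level inference).
#' @param alpha Two-sided significance level of the mask.
#' @param region_labels Optional region labels (taken from `values`
#'   dimnames by default).
#' @return Object of class `isfc_mask`.
#' @export
significance_mask <- function(values, alpha, region_labels = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(-1, 0, 1))) stop("mask values must be -1, 0 or +1")
  if (max(abs(values - t(values))) > 0) stop("mask must be symmetric")
  diag(values) <- 0
  labels <- region_labels %||% colnames(values) %||%
    default_region_labels(ncol(values))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, alpha = alpha, region_labels = labels),
            class = "isfc_mask")
}

#' @export
print.isfc_permutation_result <- function(x, ...) {
  cat(sprintf("Subject-wise permutation test: %d permutations%s, groups %s - %s\n",
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else "",
              x$group_order[1], x$group_order[2]))
  for (a in names(x$masks)) {
    v <- x$masks[[a]]$values
    cat(sprintf("  alpha %s: %d positive, %d negative significant pairs\n",
                a, sum(upper_tri_values(v) == 1), sum(upper_tri_values(v) == -1)))
  }
  invisible(x)
}

#' @export
print.isfc_mask <- function(x, ...) {
  ut <- upper_tri_values(x$values)
  cat(sprintf("Significance mask (alpha = %s): %d regions, %d +1 / %d -1 pairs\n",
              format(x$alpha), length(x$region_labels),
              sum(ut == 1), sum(ut == -1)))
  invisible(x)
}

#' Per-ROI counts of significant connections
#'
#' For each region, the number of significantly positive (+1) and negative
#' (-1) pairwise connections involving it (diagonal excluded). Summing the
#' positive counts over regions gives twice the number of +1
#' upper-triangle pairs, since each pair touches two regions.
#'
#' @param mask An `isfc_mask`.
#' @return Data frame with `region`, `positive_count`, `negative_count`.
#' @export
roi_count_map <- function(mask) {
  stopifnot(inherits(mask, "isfc_mask"))
  data.frame(region = mask$region_labels,
             positive_count = as.integer(rowSums(mask$values == 1)),
             negative_count = as.integer(rowSums(mask$values == -1)),
             row.names = NULL)
}

#' Inter-subject coupling of head motion
#'
#' Computes the Pearson correlation of framewise-displacement series for
#' every unordered subject pair and compares within-group median motion
#' coupling between the two groups with the same subject-wise permutation
#' machinery used for ISFC (scalar statistic). Near-zero couplings rule out
#' stimulus-locked motion as a driver of ISFC differences.
#'
#' @param fd_list Named list of per-subject FD vectors of equal length.
#' @param labels Group label per subject.
#' @param group_order Length-2 label order (first minus second).
#' @param n_permutations Label shuffles for the group comparison.
#' @param seed Integer seed.
#' @return List with `pair_table` (subject pair correlations),
#'   `median_within` (per-group median coupling), `observed_diff`,
#'   `p_value`, `n_permutations`.
#' @export
intersubject_motion_coupling <- function(fd_list, labels, group_order = NULL,
                                         n_permutations = 1000L, seed = NULL) {
  n <- length(fd_list)
  if (n < 4L) stop("need at least 2 subjects per group")
  labels <- as.character(labels)
  if (is.null(group_order)) group_order <- sort(unique(labels))
  ids <- names(fd_list) %||% sprintf("sub-%02d", seq_len(n))
  lens <- lengths(fd_list)
  if (any(lens != lens[1])) stop("FD series must have equal length")
  sds <- vapply(fd_list, stats::sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("constant FD series for subject(s): %s",
                 paste(ids[sds == 0], collapse = ", ")))

  fd_mat <- do.call(cbind, fd_list)
  cmat <- stats::cor(fd_mat)
  pair_i <- pair_j <- integer(0)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    pair_i <- c(pair_i, a); pair_j <- c(pair_j, b)
  }
  r_pair <- cmat[cbind(pair_i, pair_j)]
  pair_table <- data.frame(a = ids[pair_i], b = ids[pair_j],
                           correlation = r_pair)

  eng <- permutation_engine(matrix(r_pair, nrow = 1L), pair_i, pair_j,
                            labels, group_order, n_permutations, seed)
  within <- vapply(group_order, function(g) {
    sel <- labels[pair_i] == g & labels[pair_j] == g
    stats::median(r_pair[sel])
  }, numeric(1))
  p <- (1 + sum(abs(eng$nulls[1L, ]) >= abs(eng$observed[1L]))) /
    (1 + eng$n_permutations)
  list(pair_table = pair_table,
       median_within = within,
       observed_diff = unname(eng$observed[1L]),
       p_value = p,
       n_permutations = eng$n_permutations)
}
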