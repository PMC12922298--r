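#' Configuration for the two-group synthetic BOLD generator
#'
#' Defines the generative model used to emulate two groups of subjects
#' watching the same naturalistic stimulus. All subjects share one draw of a
#' latent stimulus signal per region; each subject's regional time series is
#' the latent signal scaled by a group-specific regional weight plus
#' subject-idiosyncratic white noise. Group differences in inter-subject
#' functional connectivity (ISFC) are planted through the weights, so the
#' latent stimulus itself remains genuinely shared across groups, the way a
#' single movie is.
#'
#' The latent signals are standardized to unit variance, so `noise_sd` is
#' directly interpretable as a noise-to-signal ratio. Temporal smoothness is
#' imposed by first-order autoregressive coloring applied uniformly to all
#' regions, which preserves the cross-region correlation structure
#' `stimulus_correlation`.
#'
#' @param n_regions Number of regions (R).
#' @param n_timepoints Number of time points (T).
#' @param tr_seconds Repetition time in seconds.
#' @param group_sizes Integer vector of length 2: subjects in the
#'   neurotypical-like and autism-like group, in the order of `group_labels`.
#' @param stimulus_correlation R x R unit-diagonal positive semidefinite
#'   correlation matrix of the latent stimulus signals. Default: compound
#'   symmetry with off-diagonal 0.3.
#' @param weights Named list of two numeric R-vectors in `[0, 1]`, one per
#'   group: the stimulus-response gain of each region. Default: baseline 0.7
#'   everywhere, with regions 1-5 raised to 0.9 in the first group and
#'   lowered to 0.4 in the second, planting inter-subject hypoconnectivity
#'   in the second group.
#' @param noise_sd Standard deviation of subject-idiosyncratic white noise.
#' @param smoothness Temporal autocorrelation length in TRs (0 = white).
#' @param motion_mean_fd Length-2 nonnegative vector: target mean framewise
#'   displacement (mm) per group for simulated motion.
#' @param high_mover_fraction Fraction of subjects whose mean FD is pushed
#'   above the 0.5 mm exclusion threshold.
#' @param group_labels Character vector of length 2 naming the groups; the
#'   first is the minuend of all group-difference statistics.
#' @param seed Integer seed consumed by [build_dataset()].
#'
#' @return An object of class `isfc_config`.
#' @export
synthetic_config <- function(n_regions = 15L,
                             n_timepoints = 300L,
                             tr_seconds = 2,
                             group_sizes = c(19L, 18L),
                             stimulus_correlation = NULL,
                             weights = NULL,
                             noise_sd = 1,
                             smoothness = 2,
                             motion_mean_fd = c(0.15, 0.25),
                             high_mover_fraction = 0.1,
                             group_labels = c("neurotypical", "autism"),
                             seed = 1L) {
  stopifnot_scalar_number(n_regions, "n_regions", positive = TRUE)
  stopifnot_scalar_number(n_timepoints, "n_timepoints", positive = TRUE)
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  stopifnot_scalar_number(smoothness, "smoothness", nonneg = TRUE)
  stopifnot_scalar_number(high_mover_fraction, "high_mover_fraction", nonneg = TRUE)
  if (high_mover_fraction > 1) stop("'high_mover_fraction' must be in [0, 1]")
  if (length(group_sizes) != 2L || any(group_sizes < 2L))
    stop("'group_sizes' must be two integers, each >= 2")
  if (length(motion_mean_fd) != 2L || any(motion_mean_fd < 0))
    stop("'motion_mean_fd' must be two nonnegative reals")
  if (length(group_labels) != 2L || anyDuplicated(group_labels))
    stop("'group_labels' must be two distinct labels")
  r <- as.integer(n_regions)

  if (is.null(stimulus_correlation)) {
    stimulus_correlation <- matrix(0.3, r, r)
    diag(stimulus_correlation) <- 1
  }
  validate_stimulus_correlation(stimulus_correlation, r)

  if (is.null(weights)) {
    w_base <- rep(0.7, r)
    planted <- seq_len(min(5L, r))
    w1 <- w_base; w1[planted] <- 0.9
    w2 <- w_base; w2[planted] <- 0.4
    weights <- stats::setNames(list(w1, w2), group_labels)
  }
  if (!is.list(weights) || length(weights) != 2L)
    stop("'weights' must be a list of two R-vectors")
  if (is.null(names(weights))) names(weights) <- group_labels
  weights <- weights[group_labels]
  for (g in group_labels) {
    w <- weights[[g]]
    if (length(w) != r) stop(sprintf("weights for group '%s' must have length %d", g, r))
    if (any(w < 0 | w > 1)) stop(sprintf("weights for group '%s' must lie in [0, 1]", g))
  }

  structure(
    list(n_regions = r,
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds,
         group_sizes = stats::setNames(as.integer(group_sizes), group_labels),
         stimulus_correlation = stimulus_correlation,
         weights = weights,
         noise_sd = noise_sd,
         smoothness = smoothness,
         motion_mean_fd = stats::setNames(as.numeric(motion_mean_fd), group_labels),
         high_mover_fraction = high_mover_fraction,
         group_labels = group_labels,
         seed = as.integer(seed),
         region_labels = default_region_labels(r)),
    class = "isfc_config")
}

validate_stimulus_correlation <- function(sigma, r) {
  if (!is.matrix(sigma) || nrow(sigma) != r || ncol(sigma) != r)
    stop(sprintf("'stimulus_correlation' must be a %d x %d matrix", r, r))
  if (max(abs(sigma - t(sigma))) > 1e-10)
    stop("'stimulus_correlation' must be symmetric")
  if (max(abs(diag(sigma) - 1)) > 1e-10)
    stop("'stimulus_correlation' must have a unit diagonal")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf(
      "'stimulus_correlation' is not positive semidefinite (smallest eigenvalue %.6g)",
      min(ev)))
  invisible(sigma)
}

#' @export
print.isfc_config <- function(x, ...) {
  cat("Synthetic ISFC configuration\n")
  cat(sprintf("  regions: %d, timepoints: %d (TR %.3g s)\n",
              x$n_regions, x$n_timepoints, x$tr_seconds))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n = %d)", x$group_labels, x$group_sizes),
                    collapse = ", ")))
  cat(sprintf("  noise sd: %.3g, smoothness: %.3g TR, seed: %d\n",
              x$noise_sd, x$smoothness, x$seed))
  invisible(x)
}

#' Sample the shared latent stimulus signal
#'
#' Draws a T x R matrix of latent Gaussian signals with cross-region
#' correlation `config$stimulus_correlation` and first-order autoregressive
#' temporal coloring with autocorrelation length `config$smoothness` (in
#' TRs). The AR coefficient is `exp(-1 / smoothness)`; innovations are scaled
#' so each column is stationary with unit variance, and because the coloring
#' is applied uniformly to all columns the cross-column correlation is
#' preserved.
#'
#' Uses the current R random number generator state; seed with [set.seed()]
#' or go through [build_dataset()], which seeds from `config$seed`.
#'
#' @param config An [synthetic_config()] object.
#' @return T x R numeric matrix with region-label column names.
#' @export
sample_latent_stimulus <- function(config) {
  stopifnot(inherits(config, "isfc_config"))
  r <- config$n_regions
  tt <- config$n_timepoints
  if (tt < 2L) stop("need at least 2 timepoints")
  eg <- eigen(config$stimulus_correlation, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  sq <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  innov <- matrix(stats::rnorm(tt * r), tt, r) %*% sq
  phi <- if (config$smoothness > 0) exp(-1 / config$smoothness) else 0
  if (phi > 0) {
    a <- sqrt(1 - phi^2)
    out <- innov
    for (t in 2:tt) out[t, ] <- phi * out[t - 1L, ] + a * innov[t, ]
    innov <- out
  }
  colnames(innov) <- config$region_labels
  innov
}

#' Synthesize one subject's regional time series
#'
#' `x[t, r] = weights[r] * latent[t, r] + noise_sd * e[t, r]` with `e`
#' independent standard Gaussian noise, drawn independently per subject.
#'
#' @param latent T x R latent-signal matrix from [sample_latent_stimulus()].
#' @param weights Numeric R-vector of regional stimulus gains.
#' @param noise_sd Positive noise standard deviation.
#' @return T x R numeric matrix.
#' @export
synthesize_subject <- function(latent, weights, noise_sd) {
  latent <- as.matrix(latent)
  if (length(weights) != ncol(latent))
    stop(sprintf("length(weights) = %d but latent has %d regions",
                 length(weights), ncol(latent)))
  stopifnot_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  noise <- matrix(stats::rnorm(length(latent), sd = noise_sd),
                  nrow(latent), ncol(latent))
  out <- sweep(latent, 2L, weights, "*") + noise
  colnames(out) <- colnames(latent)
  out
}

#' Closed-form expected pairwise ISFC under the generative model
#'
#' For two different subjects of the same group, the population correlation
#' between subject a's region-i series and subject b's region-j series is
#' \deqn{\rho_{ij} = \frac{w_i w_j \Sigma_{ij}}{\sqrt{(w_i^2 + \sigma^2)(w_j^2 + \sigma^2)}}}
#' because only the shared latent stimulus is common to the two subjects.
#' The diagonal (i = j) is the expected inter-subject correlation of a
#' region with itself across subjects.
#'
#' @param config An [synthetic_config()] object.
#' @param group One of `config$group_labels`.
#' @return Symmetric R x R matrix of expected ISFC values.
#' @export
expected_pairwise_isfc <- function(config, group) {
  stopifnot(inherits(config, "isfc_config"))
  group <- match.arg(group, config$group_labels)
  w <- config$weights[[group]]
  s2 <- config$noise_sd^2
  denom <- sqrt(w^2 + s2)
  rho <- (outer(w, w) * config$stimulus_correlation) / outer(denom, denom)
  dimnames(rho) <- list(config$region_labels, config$region_labels)
  rho
}

#' Generate a complete two-group synthetic dataset
#'
#' Seeds the RNG from `config$seed` (restoring the caller's RNG state on
#' exit), draws one shared latent stimulus, synthesizes every subject's
#' series and motion confounds, and attaches the closed-form expected ISFC
#' for both groups together with the list of planted group-difference pairs
#' (all region pairs where the two groups' expected ISFC differ by more than
#' 1e-12, signed as first group minus second group).
#'
#' @param config An [synthetic_config()] object.
#' @return An object of class `isfc_dataset`: list with `subjects` (each a
#'   list of `subject_id`, `group`, `data`), `confounds` (per-subject
#'   confound data frames), `truth_expected_isfc` (one matrix per group),
#'   `planted_pairs` (data frame `i`, `j`, `direction`), and `config`.
#' @export
build_dataset <- function(config) {
  stopifnot(inherits(config, "isfc_config"))
  with_seed(config$seed, {
    latent <- sample_latent_stimulus(config)
    groups <- rep(config$group_labels, times = config$group_sizes)
    n <- length(groups)
    ids <- sprintf("sub-%02d", seq_len(n))
    subjects <- vector("list", n)
    for (k in seq_len(n)) {
      subjects[[k]] <- list(
        subject_id = ids[k],
        group = groups[k],
        data = synthesize_subject(latent, config$weights[[groups[k]]],
                                  config$noise_sd))
    }
    confounds <- sample_motion_confounds(config, groups = groups, ids = ids)

    truth <- lapply(config$group_labels, function(g) expected_pairwise_isfc(config, g))
    names(truth) <- config$group_labels
    gap <- truth[[1L]] - truth[[2L]]
    pairs <- upper_tri_pairs(config$n_regions)
    gap_ut <- upper_tri_values(gap)
    planted <- pairs[abs(gap_ut) > 1e-12, , drop = FALSE]
    planted$direction <- sign(gap_ut[abs(gap_ut) > 1e-12])
    rownames(planted) <- NULL

    structure(
      list(subjects = subjects,
           confounds = confounds,
           truth_expected_isfc = truth,
           planted_pairs = planted,
           config = config),
      class = "isfc_dataset")
  })
}

#' @export
print.isfc_dataset <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("Synthetic ISFC dataset: %d subjects (%s), %d regions x %d timepoints\n",
              length(x$subjects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$config$n_regions, x$config$n_timepoints))
  cat(sprintf("  planted group-difference pairs: %d\n", nrow(x$planted_pairs)))
  invisible(x)
}

#' Simulate per-subject motion confound tables
#'
#' Each subject gets six motion-parameter random walks (translations in mm,
#' rotations in radians) rescaled so the mean Power-style framewise
#' displacement hits the subject's target exactly (mean FD is linear in a
#' global step-size factor, so the rescaling is closed-form). Targets are
#' the group's `motion_mean_fd`; a `high_mover_fraction` of subjects
#' (rounded) is instead pushed above the 0.5 mm exclusion threshold.
#' White-matter and CSF nuisance signals are autocorrelated noise
#' independent of the latent stimulus; motion is independent across
#' subjects. Tables use fMRIPrep-dialect column names.
#'
#' Uses the current RNG state; [build_dataset()] seeds it from the config.
#'
#' @param config An [synthetic_config()] object.
#' @param groups Optional group label per subject (defaults to the config's
#'   group blocks in order).
#' @param ids Optional subject ids.
#' @return Named list of per-subject confound data frames.
#' @export
sample_motion_confounds <- function(config, groups = NULL, ids = NULL) {
  stopifnot(inherits(config, "isfc_config"))
  tt <- config$n_timepoints
  if (is.null(groups)) groups <- rep(config$group_labels, times = config$group_sizes)
  n <- length(groups)
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_len(n))

  n_high <- round(config$high_mover_fraction * n)
  high <- rep(FALSE, n)
  if (n_high > 0) high[sample.int(n, n_high)] <- TRUE

  dct <- build_dct_basis(tt, config$tr_seconds)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    target <- if (high[k]) {
      max(0.7, 1.5 * config$motion_mean_fd[[groups[k]]])
    } else {
      config$motion_mean_fd[[groups[k]]]
    }
    motion <- apply(matrix(stats::rnorm(tt * 6L), tt, 6L), 2L, cumsum)
    # rotations move less than translations before FD scaling
    motion[, 4:6] <- motion[, 4:6] / 50
    fd0 <- mean(framewise_displacement(motion))
    if (target > 0 && fd0 > 0) motion <- motion * (target / fd0)
    else motion[] <- 0
    fd <- framewise_displacement(motion)

    ar_noise <- function() {
      as.numeric(stats::filter(stats::rnorm(tt) * sqrt(1 - 0.5^2), 0.5,
                               method = "recursive", init = stats::rnorm(1)))
    }
    df <- data.frame(trans_x = motion[, 1], trans_y = motion[, 2],
                     trans_z = motion[, 3], rot_x = motion[, 4],
                     rot_y = motion[, 5], rot_z = motion[, 6],
                     csf = ar_noise(), white_matter = ar_noise(),
                     framewise_displacement = fd,
                     std_dvars = c(0, 1 + 0.1 * abs(stats::rnorm(tt - 1L))))
    if (ncol(dct) > 0) {
      colnames(dct) <- sprintf("cosine%02d", seq_len(ncol(dct)) - 1L)
      df <- cbind(df, dct)
    }
    out[[k]] <- df
  }
  names(out) <- ids
  out
}
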