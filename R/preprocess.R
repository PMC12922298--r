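#' Power-style framewise displacement
#'
#' FD at frame t is the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius_mm` times the sum of absolute
#' backward differences of the three rotations (radians), the fMRIPrep
#' convention. The first frame has FD 0 by definition.
#'
#' @param motion T x 6 matrix or data frame: translations x/y/z then
#'   rotations x/y/z.
#' @param head_radius_mm Radius used to convert rotations to arc length.
#' @return Nonnegative numeric T-vector, first element 0.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("framewise displacement needs at least 2 frames")
  if (ncol(motion) != 6L) stop("'motion' must have 6 columns (3 translations, 3 rotations)")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Exclude subjects by mean framewise displacement
#'
#' Subjects whose mean FD is strictly greater than `threshold` (0.5 mm by
#' default) are dropped; a subject sitting exactly on the threshold is
#' retained.
#'
#' @param fd_list Named list of per-subject FD vectors (or confound data
#'   frames containing a `framewise_displacement` column).
#' @param threshold Mean-FD exclusion threshold in mm.
#' @return List with `kept` (names of retained subjects) and `report`
#'   (data frame `subject_id`, `mean_fd`, `excluded`).
#' @export
mean_fd_exclusion <- function(fd_list, threshold = 0.5) {
  if (!length(fd_list)) stop("empty subject list")
  fd_of <- function(x) {
    if (is.data.frame(x)) {
      if (is.null(x$framewise_displacement))
        stop("confound table lacks a 'framewise_displacement' column")
      x$framewise_displacement
    } else as.numeric(x)
  }
  ids <- names(fd_list) %||% sprintf("sub-%02d", seq_along(fd_list))
  mfd <- vapply(fd_list, function(x) mean(fd_of(x)), numeric(1))
  excluded <- mfd > threshold
  if (all(excluded)) stop("all subjects excluded by the mean-FD threshold")
  report <- data.frame(subject_id = ids, mean_fd = as.numeric(mfd),
                       excluded = as.logical(excluded), row.names = NULL)
  list(kept = ids[!excluded], report = report)
}

#' Discrete cosine transform high-pass basis
#'
#' Returns the K non-constant discrete cosine columns whose periods exceed
#' `cutoff_seconds`, with `K = floor(2 * T * tr_seconds / cutoff_seconds)`.
#' Columns are mutually orthogonal; including them as nuisance regressors
#' removes fluctuations slower than the cutoff.
#'
#' @param n_timepoints Number of frames T (>= 2).
#' @param tr_seconds Repetition time in seconds.
#' @param cutoff_seconds High-pass cutoff period (fMRIPrep default 128 s).
#' @return T x K numeric matrix (K may be 0, with a warning).
#' @export
build_dct_basis <- function(n_timepoints, tr_seconds, cutoff_seconds = 128) {
  stopifnot_scalar_number(cutoff_seconds, "cutoff_seconds", positive = TRUE)
  tt <- as.integer(n_timepoints)
  if (tt < 2L) stop("need at least 2 timepoints")
  k_max <- floor(2 * tt * tr_seconds / cutoff_seconds)
  if (k_max < 1) {
    warning("run too short for the high-pass cutoff; returning an empty DCT basis")
    return(matrix(numeric(0), tt, 0L))
  }
  t_idx <- seq_len(tt) - 0.5
  basis <- vapply(seq_len(k_max),
                  function(k) sqrt(2 / tt) * cos(pi * k * t_idx / tt),
                  numeric(tt))
  basis
}

#' Clean a subject's regional time series by joint confound regression
#'
#' Reproduces the post-fMRIPrep cleaning chain: a single least-squares fit
#' per region of the design `[intercept, linear trend, 6 motion parameters,
#' white matter, CSF, DCT high-pass basis]`, followed by shifting the
#' residuals to zero mean and scaling each region by its sample (T - 1)
#' standard deviation. All regressors are fitted jointly in one pass;
#' sequential residualization would be order-dependent.
#'
#' @param series T x R numeric matrix (columns = regions).
#' @param confounds Confound data frame in the fMRIPrep dialect (see
#'   [read_confounds()]), or a list with elements `motion` (T x 6),
#'   `wm_signal`, `csf_signal`, and optionally `cosine_basis`.
#' @param subject_id,group Carried through to the result.
#' @param dct_basis Optional T x K DCT basis; by default the cosine columns
#'   found in `confounds` are used, or none.
#' @return Object of class `cleaned_series`: list with standardized `data`
#'   (each column mean 0, sample sd 1, orthogonal to every design column),
#'   `subject_id`, `group`.
#' @export
regress_confounds <- function(series, confounds, subject_id = NA_character_,
                              group = NA_character_, dct_basis = NULL) {
  series <- as.matrix(series)
  tt <- nrow(series)
  design <- confound_design(confounds, tt, dct_basis)
  if (nrow(design) != tt)
    stop(sprintf("series has %d frames but confounds have %d", tt, nrow(design)))

  # constant columns are spanned by the intercept; keep the fit full-rank
  rng <- apply(design, 2L, function(v) max(v) - min(v))
  design <- design[, c(TRUE, rng[-1L] > 1e-12), drop = FALSE]

  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop(sprintf("rank-deficient confound design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  resid <- qr.resid(qrd, series)

  s <- sqrt(colSums(sweep(resid, 2L, colMeans(resid), "-")^2) / (tt - 1L))
  bad <- which(s < 1e-10)
  if (length(bad)) {
    lab <- colnames(series)[bad] %||% bad
    stop(sprintf("zero residual variance in region(s): %s",
                 paste(lab, collapse = ", ")))
  }
  cleaned <- standardize_columns(resid, context = "cleaned series")
  colnames(cleaned) <- colnames(series)
  structure(list(data = cleaned, subject_id = subject_id, group = group),
            class = "cleaned_series")
}

# Assemble the joint design matrix from either a confound data frame in the
# fMRIPrep dialect or a structured list.
confound_design <- function(confounds, tt, dct_basis = NULL) {
  if (is.data.frame(confounds)) {
    need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
              "csf", "white_matter")
    missing_cols <- setdiff(need, names(confounds))
    if (length(missing_cols))
      stop(sprintf("confound table missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
    motion <- as.matrix(confounds[need[1:6]])
    wm <- confounds$white_matter
    csf <- confounds$csf
    if (is.null(dct_basis)) {
      cos_cols <- grep("^cosine", names(confounds), value = TRUE)
      dct_basis <- if (length(cos_cols)) as.matrix(confounds[cos_cols])
                   else matrix(numeric(0), nrow(confounds), 0L)
    }
  } else if (is.list(confounds)) {
    motion <- as.matrix(confounds$motion)
    wm <- confounds$wm_signal
    csf <- confounds$csf_signal
    if (is.null(dct_basis))
      dct_basis <- confounds$cosine_basis %||% matrix(numeric(0), nrow(motion), 0L)
  } else stop("'confounds' must be a data frame or list")

  design <- cbind(intercept = 1,
                  trend = seq_len(tt) - (tt + 1) / 2,
                  motion, wm = wm, csf = csf, dct_basis)
  colnames(design)[3:8] <- c("trans_x", "trans_y", "trans_z",
                             "rot_x", "rot_y", "rot_z")
  k <- ncol(design) - 10L
  if (k > 0) colnames(design)[10L + seq_len(k)] <- sprintf("cosine%02d", seq_len(k) - 1L)
  design
}

#' @export
print.cleaned_series <- function(x, ...) {
  cat(sprintf("Cleaned series: subject %s (%s), %d timepoints x %d regions\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data)))
  invisible(x)
}
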