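#' Read a subject's ROI-by-time table
#'
#' Tab-separated, one header row of region labels, T numeric rows. Ragged
#' rows, non-numeric cells, missing values and duplicate region labels are
#' rejected with the offending location.
#'
#' @param path File path.
#' @return T x R numeric matrix with region-label column names.
#' @export
read_timeseries_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, fields[bad], fields[1]))
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  labels <- names(df)
  if (anyDuplicated(labels))
    stop(sprintf("%s: duplicate region label(s): %s", path,
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  mat <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, labels))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric or missing value at data row %d, column '%s'",
                   path, bad[1], labels[j]))
    mat[, j] <- v
  }
  mat
}

#' Write a subject's ROI-by-time table
#'
#' @param mat T x R numeric matrix; column names become the header.
#' @param path Output path.
#' @export
write_timeseries_table <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- default_region_labels(ncol(mat))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  utils::write.table(chr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an fMRIPrep-dialect confound table
#'
#' Requires the six motion parameters (`trans_x` ... `rot_z`) plus `csf`
#' and `white_matter`; `framewise_displacement`, `std_dvars` and `cosine*`
#' columns are used when present. fMRIPrep writes `n/a` in the first row of
#' difference-based columns; those are parsed as 0. If the FD column is
#' absent it is recomputed from the motion parameters; if cosine columns
#' are absent the high-pass basis can be rebuilt with [build_dct_basis()].
#'
#' @param path File path.
#' @return Confound data frame.
#' @export
read_confounds <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, na.strings = c("n/a", "NA"), check.names = FALSE)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "csf", "white_matter")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required confound column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  for (col in c("framewise_displacement", "std_dvars"))
    if (col %in% names(df) && is.na(df[[col]][1])) df[[col]][1] <- 0
  if (anyNA(df[need])) stop(sprintf("%s: missing values in required columns", path))
  if (is.null(df$framewise_displacement))
    df$framewise_displacement <- framewise_displacement(df[need[1:6]])
  df
}

#' Write a confound table in the fMRIPrep dialect
#'
#' The first row of `framewise_displacement` and `std_dvars` is written as
#' `n/a`, matching fMRIPrep output.
#'
#' @param confounds Confound data frame.
#' @param path Output path.
#' @export
write_confounds <- function(confounds, path) {
  out <- confounds
  for (col in c("framewise_displacement", "std_dvars"))
    if (col %in% names(out)) out[[col]] <- c("n/a", sprintf("%.10g", out[[col]][-1]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits one ROI-by-time TSV and one confound TSV per subject plus a JSON
#' manifest mapping subject ids to group labels and file paths.
#'
#' @param dataset An `isfc_dataset` from [build_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "isfc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(dataset$subjects, function(s) {
    ts_path <- file.path(dir, sprintf("%s_timeseries.tsv", s$subject_id))
    cf_path <- file.path(dir, sprintf("%s_confounds.tsv", s$subject_id))
    write_timeseries_table(s$data, ts_path)
    write_confounds(dataset$confounds[[s$subject_id]], cf_path)
    list(subject_id = s$subject_id, group = s$group,
         timeseries = basename(ts_path), confounds = basename(cf_path))
  })
  manifest <- list(seed = dataset$config$seed,
                   n_regions = dataset$config$n_regions,
                   n_timepoints = dataset$config$n_timepoints,
                   tr_seconds = dataset$config$tr_seconds,
                   group_labels = dataset$config$group_labels,
                   subjects = entries)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset manifest and its subject tables
#'
#' Checks that all subjects share the same region labels in the same order.
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_dataset()].
#' @return List with `subjects` (id, group, data matrix), `confounds`,
#'   and the manifest metadata.
#' @export
read_dataset <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  subjects <- list(); confounds <- list()
  labels_ref <- NULL
  for (e in manifest$subjects) {
    mat <- read_timeseries_table(file.path(dir, e$timeseries))
    if (is.null(labels_ref)) labels_ref <- colnames(mat)
    else if (!identical(labels_ref, colnames(mat)))
      stop(sprintf("subject %s: region labels differ from the rest of the cohort",
                   e$subject_id))
    subjects[[e$subject_id]] <- list(subject_id = e$subject_id,
                                     group = e$group, data = mat)
    confounds[[e$subject_id]] <- read_confounds(file.path(dir, e$confounds))
  }
  list(subjects = subjects, confounds = confounds,
       group_labels = unlist(manifest$group_labels),
       tr_seconds = manifest$tr_seconds,
       seed = manifest$seed)
}

#' Write a symmetric matrix as a labelled TSV
#'
#' @param mat R x R matrix with region-label dimnames.
#' @param path Output path.
#' @export
write_matrix_table <- function(mat, path) {
  utils::write.table(as.matrix(mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Flat unique-pair table of a group summary
#'
#' @param summary An `isfc_group_summary`.
#' @return Data frame `region_i`, `region_j`, `median_isfc` over the
#'   R(R-1)/2 unique pairs.
#' @export
unique_pair_table <- function(summary) {
  stopifnot(inherits(summary, "isfc_group_summary"))
  pairs <- upper_tri_pairs(length(summary$region_labels))
  data.frame(region_i = summary$region_labels[pairs$i],
             region_j = summary$region_labels[pairs$j],
             median_isfc = summary$unique_values)
}
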