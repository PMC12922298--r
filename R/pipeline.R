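#' Default run configuration for the two-dataset pipeline
#'
#' A run analyses two datasets — one labelled `discovery`, one
#' `replication` (the discovery dataset defines the denominator of the
#' replication rate) — each either simulated from a [synthetic_config()] or
#' loaded from a written manifest.
#'
#' @param seed Global integer seed; every randomized stage derives its own
#'   sub-seed from it and records it in the outputs.
#' @param output_dir Output directory.
#' @param n_permutations Label shuffles per dataset for the group test.
#' @param n_shuffles Region shuffles for the replication statistics.
#' @param alphas Two-sided significance levels.
#' @param fd_threshold Mean-FD subject exclusion threshold (mm).
#' @param discovery,replication Lists of [synthetic_config()] arguments (or
#'   ready `isfc_config` objects) for the two simulated datasets.
#' @return A `list` of class `isfc_run_config`.
#' @export
default_run_config <- function(seed = 1L, output_dir = "isfc_run",
                               n_permutations = 1000L, n_shuffles = 1000L,
                               alphas = c(0.05, 0.01), fd_threshold = 0.5,
                               discovery = list(), replication = list()) {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 n_permutations = as.integer(n_permutations),
                 n_shuffles = as.integer(n_shuffles),
                 alphas = alphas, fd_threshold = fd_threshold,
                 discovery = discovery, replication = replication),
            class = "isfc_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [default_run_config()];
#' `discovery:` and `replication:` blocks hold [synthetic_config()]
#' arguments (a `stimulus_correlation` given as a single number is expanded
#' to a compound-symmetry matrix).
#'
#' @param path YAML file path.
#' @return An `isfc_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(default_run_config)))]
  for (ds in c("discovery", "replication")) {
    blk <- args[[ds]] %||% list()
    if (!is.null(blk$weights)) blk$weights <- lapply(blk$weights, as.numeric)
    if (length(blk$stimulus_correlation) == 1L && !is.null(blk$n_regions)) {
      r <- blk$n_regions
      s <- matrix(as.numeric(blk$stimulus_correlation), r, r); diag(s) <- 1
      blk$stimulus_correlation <- s
    }
    args[[ds]] <- blk
  }
  do.call(default_run_config, args)
}

#' Run the full two-dataset ISFC pipeline
#'
#' Executes simulate, FD-based exclusion, confound cleaning, pairwise ISFC
#' with median group summaries, the subject-wise permutation test per
#' dataset, and the cross-dataset replication statistics; writes every
#' artifact (tab-separated matrices, signed masks, count maps, JSON
#' sidecars with seeds and sizes) plus a manifest with MD5 hashes of all
#' outputs. Re-running with the same configuration and seed reproduces
#' byte-identical files.
#'
#' @param config An `isfc_run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @param output_dir Overrides `config$output_dir` when non-NULL.
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with the per-dataset results, the replication
#'   summary, and the manifest path.
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "isfc_run_config"))
  out_root <- output_dir %||% config$output_dir
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_root, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  say("[config] seed = %d, n_permutations = %d, n_shuffles = %d",
      config$seed, config$n_permutations, config$n_shuffles)

  results <- list()
  for (idx in 1:2) {
    ds_name <- c("discovery", "replication")[idx]
    ds_dir <- file.path(out_root, ds_name)
    dir.create(ds_dir, recursive = TRUE, showWarnings = FALSE)

    blk <- config[[ds_name]]
    syn_cfg <- if (inherits(blk, "isfc_config")) blk else {
      blk$seed <- blk$seed %||% (config$seed + 100L * idx)
      do.call(synthetic_config, blk)
    }
    say("[%s] simulating: R = %d, T = %d, groups %s", ds_name,
        syn_cfg$n_regions, syn_cfg$n_timepoints,
        paste(syn_cfg$group_sizes, collapse = "+"))
    dataset <- build_dataset(syn_cfg)
    write_dataset(dataset, file.path(ds_dir, "data"))

    excl <- mean_fd_exclusion(dataset$confounds, threshold = config$fd_threshold)
    utils::write.table(excl$report, file.path(ds_dir, "fd_exclusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("[%s] FD exclusion: %d of %d subjects retained (threshold %.2f mm)",
        ds_name, length(excl$kept), length(dataset$subjects), config$fd_threshold)

    kept <- Filter(function(s) s$subject_id %in% excl$kept, dataset$subjects)
    cleaned <- lapply(kept, function(s)
      regress_confounds(s$data, dataset$confounds[[s$subject_id]],
                        subject_id = s$subject_id, group = s$group))

    groups <- syn_cfg$group_labels
    say("[%s] unique region pairs: %d", ds_name,
        unique_pair_count(syn_cfg$n_regions))
    summaries <- lapply(groups, function(g) {
      subj_g <- Filter(function(s) s$group == g, cleaned)
      sm <- median_isfc(group_pairwise_isfc(subj_g), group = g)
      write_matrix_table(sm$median_matrix,
                         file.path(ds_dir, sprintf("median_isfc_%s.tsv", g)))
      utils::write.table(unique_pair_table(sm),
                         file.path(ds_dir, sprintf("median_isfc_%s_pairs.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sm
    })
    names(summaries) <- groups

    pool <- pooled_pair_tensor(cleaned, group_order = groups)
    perm_seed <- config$seed + 10L + idx
    perm <- suppressWarnings(
      subject_wise_permutation_test(pool, n_permutations = config$n_permutations,
                                    alphas = config$alphas, seed = perm_seed))
    write_matrix_table(perm$observed_diff, file.path(ds_dir, "isfc_difference.tsv"))
    write_matrix_table(perm$p_values, file.path(ds_dir, "p_values.tsv"))
    for (a in names(perm$masks)) {
      write_matrix_table(perm$masks[[a]]$values,
                         file.path(ds_dir, sprintf("mask_alpha_%s.tsv", a)))
      utils::write.table(roi_count_map(perm$masks[[a]]),
                         file.path(ds_dir, sprintf("roi_counts_alpha_%s.tsv", a)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(dataset = ds_name, seed = perm_seed,
           n_permutations = perm$n_permutations,
           exhaustive = perm$exhaustive,
           group_sizes = as.list(stats::setNames(as.integer(perm$group_sizes),
                                                 groups)),
           alphas = config$alphas,
           n_significant = lapply(perm$masks, function(m)
             sum(upper_tri_values(m$values) != 0))),
      file.path(ds_dir, "permutation_test.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    n_sig <- sum(upper_tri_values(perm$masks[[1]]$values) != 0)
    say("[%s] permutation test: %d significant pairs at alpha %s", ds_name,
        n_sig, names(perm$masks)[1])
    results[[ds_name]] <- list(config = syn_cfg, exclusion = excl,
                               summaries = summaries, permutation = perm)
  }

  alpha1 <- format(config$alphas[1], trim = TRUE)
  rep_res <- replication_result(
    results$discovery$permutation$masks[[alpha1]],
    results$replication$permutation$masks[[alpha1]],
    diff_discovery = results$discovery$permutation$observed_diff,
    diff_replication = results$replication$permutation$observed_diff,
    n_shuffles = config$n_shuffles, seed = config$seed + 21L)
  rep_dir <- file.path(out_root, "replication_summary")
  dir.create(rep_dir, showWarnings = FALSE)
  write_matrix_table(rep_res$overlap, file.path(rep_dir, "overlap.tsv"))
  utils::write.table(rep_res$replicated_pairs,
                     file.path(rep_dir, "replicated_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(rate = rep_res$rate, p_value = rep_res$p_value,
         n_shuffles = rep_res$n_shuffles, seed = config$seed + 21L,
         pearson_r = rep_res$cross_correlation$pearson_r,
         pearson_p = rep_res$cross_correlation$p_value),
    file.path(rep_dir, "replication.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[replicate] rate = %.3f (p = %.4g), cross-dataset r = %.3f (p = %.4g)",
      rep_res$rate, rep_res$p_value,
      rep_res$cross_correlation$pearson_r, rep_res$cross_correlation$p_value)

  files <- setdiff(list.files(out_root, recursive = TRUE),
                   c("manifest.json", "pipeline.log"))
  manifest <- list(
    seed = config$seed,
    n_permutations = config$n_permutations,
    n_shuffles = config$n_shuffles,
    files = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(out_root, f))))))
  manifest_path <- file.path(out_root, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("[done] %d artifacts written to %s", length(files), out_root)

  invisible(list(discovery = results$discovery,
                 replication = results$replication,
                 replication_summary = rep_res,
                 manifest = manifest_path))
}
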