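make_cleaned <- function(mat, id, group) {
  structure(list(data = isfcr:::standardize_columns(mat), subject_id = id,
                 group = group), class = "cleaned_series")
}

test_that("pooled tensor restricts to the per-group tensors bit-exactly", {
  set.seed(301)
  mats <- replicate(5, matrix(rnorm(60 * 4), 60, 4), simplify = FALSE)
  subjects <- Map(make_cleaned, mats, sprintf("s%d", 1:5),
                  c("nt", "nt", "nt", "aut", "aut"))
  pool <- pooled_pair_tensor(subjects, group_order = c("nt", "aut"))
  expect_identical(ncol(pool$values), 10L)  # 5 choose 2

  within_nt <- pool$labels[pool$pair_i] == "nt" & pool$labels[pool$pair_j] == "nt"
  grp <- group_pairwise_isfc(subjects[1:3])
  for (k in seq_len(3)) {
    expect_identical(pool$values[, which(within_nt)[k]],
                     isfcr:::flatten_sym(grp$matrices[, , k]))
  }

  expect_error(pooled_pair_tensor(subjects[c(1, 4, 5)],
                                  group_order = c("nt", "aut")),
               "at least 2")
})

test_that("identical groups produce a zero observed difference and empty masks", {
  set.seed(302)
  mats <- replicate(4, matrix(rnorm(80 * 5), 80, 5), simplify = FALSE)
  subjects <- c(Map(make_cleaned, mats, sprintf("a%d", 1:4), "g1"),
                Map(make_cleaned, mats, sprintf("b%d", 1:4), "g2"))
  pool <- pooled_pair_tensor(subjects, group_order = c("g1", "g2"))
  res <- suppressWarnings(
    subject_wise_permutation_test(pool, n_permutations = 200, seed = 1))
  expect_equal(max(abs(res$observed_diff)), 0)
  expect_true(all(res$masks[["0.05"]]$values == 0))
  expect_true(all(res$p_values > 0 & res$p_values <= 1))
})

test_that("exhaustive enumeration engages for small shuffle spaces, with a warning", {
  set.seed(303)
  mats <- replicate(6, matrix(rnorm(50 * 3), 50, 3), simplify = FALSE)
  subjects <- Map(make_cleaned, mats, sprintf("s%d", 1:6),
                  rep(c("g1", "g2"), each = 3))
  pool <- pooled_pair_tensor(subjects, group_order = c("g1", "g2"))
  expect_warning(
    res <- subject_wise_permutation_test(pool, n_permutations = 500, seed = 1),
    "enumerating")
  expect_identical(res$n_permutations, as.integer(choose(6, 3)))
  expect_true(res$exhaustive)
  # the identity assignment appears in the null: one column equals observed
  obs <- isfcr:::flatten_sym(res$observed_diff)
  eng <- suppressWarnings(
    isfcr:::permutation_engine(pool$values, pool$pair_i, pool$pair_j,
                               pool$labels, pool$group_order, 500, 1))
  expect_true(any(apply(eng$nulls, 2, function(v) isTRUE(all.equal(v, obs)))))
})

test_that("swapping group labels flips the sign of statistic and mask", {
  cfg <- synthetic_config(n_regions = 8, n_timepoints = 150,
                          group_sizes = c(6, 6), seed = 40)
  ds <- build_dataset(cfg)
  cl <- clean_all(ds)
  pool_ab <- pooled_pair_tensor(cl, group_order = cfg$group_labels)
  pool_ba <- pooled_pair_tensor(cl, group_order = rev(cfg$group_labels))
  res_ab <- suppressWarnings(
    subject_wise_permutation_test(pool_ab, n_permutations = 300, seed = 5))
  res_ba <- suppressWarnings(
    subject_wise_permutation_test(pool_ba, n_permutations = 300, seed = 5))
  expect_equal(res_ab$observed_diff, -res_ba$observed_diff)
  expect_equal(res_ab$masks[["0.05"]]$values, -res_ba$masks[["0.05"]]$values)
})

test_that("permutation results are reproducible for a fixed seed", {
  cfg <- synthetic_config(n_regions = 6, n_timepoints = 120,
                          group_sizes = c(5, 5), seed = 41)
  ds <- build_dataset(cfg)
  cl <- clean_all(ds)
  pool <- pooled_pair_tensor(cl, group_order = cfg$group_labels)
  r1 <- suppressWarnings(
    subject_wise_permutation_test(pool, n_permutations = 200, seed = 99))
  r2 <- suppressWarnings(
    subject_wise_permutation_test(pool, n_permutations = 200, seed = 99))
  expect_identical(r1, r2)
})

test_that("ROI count maps match exhaustive enumeration", {
  r <- 10
  m0 <- significance_mask(matrix(0, r, r), 0.05)
  cm0 <- roi_count_map(m0)
  expect_true(all(cm0$positive_count == 0 & cm0$negative_count == 0))

  m1 <- mask_from_pairs(r, list(list(2, 7, 1)))
  cm1 <- roi_count_map(m1)
  expect_identical(cm1$positive_count[c(2, 7)], c(1L, 1L))
  expect_identical(sum(cm1$positive_count), 2L)

  set.seed(304)
  mr <- random_mask(r, density = 0.45)
  cm <- roi_count_map(mr)
  for (reg in seq_len(r)) {
    expect_identical(cm$positive_count[reg],
                     sum(mr$values[reg, -reg] == 1))
    expect_identical(cm$negative_count[reg],
                     sum(mr$values[reg, -reg] == -1))
  }
  n_pos_pairs <- sum(isfcr:::upper_tri_values(mr$values) == 1)
  expect_identical(sum(cm$positive_count), 2L * n_pos_pairs)
})

test_that("motion coupling is near zero for independent motion and flags identical motion", {
  cfg <- synthetic_config(n_regions = 3, n_timepoints = 300,
                          group_sizes = c(5, 5), high_mover_fraction = 0,
                          seed = 42)
  set.seed(305)
  conf <- sample_motion_confounds(cfg)
  fd <- lapply(conf, `[[`, "framewise_displacement")
  labels <- rep(cfg$group_labels, times = cfg$group_sizes)
  res <- suppressWarnings(
    intersubject_motion_coupling(fd, labels, group_order = cfg$group_labels,
                                 n_permutations = 200, seed = 1))
  expect_lt(abs(median(res$pair_table$correlation)), 3 / sqrt(300))
  expect_gt(res$p_value, 0.05)

  fd_same <- rep(fd[1], 6)
  names(fd_same) <- sprintf("s%d", 1:6)
  res_same <- suppressWarnings(
    intersubject_motion_coupling(fd_same, rep(c("a", "b"), each = 3),
                                 n_permutations = 100, seed = 1))
  expect_true(all(res_same$pair_table$correlation == 1))

  fd_const <- fd; fd_const[[2]] <- rep(0.3, 300)
  expect_error(
    intersubject_motion_coupling(fd_const, labels,
                                 group_order = cfg$group_labels),
    "constant FD.*sub-02")
})

test_that("group comparison of motion coupling is calibrated under the null", {
  set.seed(306)
  p_over <- replicate(60, {
    fd <- replicate(12, abs(rnorm(150)) + 0.1, simplify = FALSE)
    names(fd) <- sprintf("s%02d", 1:12)
    res <- intersubject_motion_coupling(fd, rep(c("a", "b"), each = 6),
                                        n_permutations = 150)
    res$p_value > 0.05
  })
  expect_gte(mean(p_over), 0.9)
})
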