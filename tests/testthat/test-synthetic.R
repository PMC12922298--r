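test_that("latent stimulus reproduces the requested cross-region correlation", {
  # independence case
  cfg <- synthetic_config(n_regions = 4, n_timepoints = 10000,
                          stimulus_correlation = diag(4), smoothness = 0,
                          group_sizes = c(2, 2), seed = 1)
  set.seed(11)
  lat <- sample_latent_stimulus(cfg)
  cc <- cor(lat)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  expect_lt(max(abs(colMeans(lat))), 0.05)
  expect_lt(max(abs(apply(lat, 2, sd) - 1)), 0.05)

  # single planted correlation recovered by Monte Carlo
  s <- diag(4); s[1, 2] <- s[2, 1] <- 0.5
  cfg2 <- synthetic_config(n_regions = 4, n_timepoints = 20000,
                           stimulus_correlation = s, smoothness = 0,
                           group_sizes = c(2, 2), seed = 1)
  set.seed(12)
  lat2 <- sample_latent_stimulus(cfg2)
  expect_lt(abs(cor(lat2[, 1], lat2[, 2]) - 0.5), 0.03)

  # AR(1) coloring preserves the cross-column correlation
  cfg3 <- synthetic_config(n_regions = 4, n_timepoints = 20000,
                           stimulus_correlation = s, smoothness = 2,
                           group_sizes = c(2, 2), seed = 1)
  set.seed(13)
  lat3 <- sample_latent_stimulus(cfg3)
  expect_lt(abs(cor(lat3[, 1], lat3[, 2]) - 0.5), 0.05)
  # and induces the expected lag-1 autocorrelation exp(-1/smoothness)
  ac <- cor(lat3[-1, 1], lat3[-nrow(lat3), 1])
  expect_lt(abs(ac - exp(-1 / 2)), 0.05)
})

test_that("latent sampler is deterministic under a fixed seed and rejects non-PSD input", {
  cfg <- synthetic_config(n_regions = 5, n_timepoints = 100,
                          group_sizes = c(2, 2), seed = 1)
  set.seed(99); a <- sample_latent_stimulus(cfg)
  set.seed(99); b <- sample_latent_stimulus(cfg)
  expect_identical(a, b)

  s <- matrix(0.9, 3, 3); diag(s) <- 1; s[1, 2] <- s[2, 1] <- -0.9
  expect_error(
    synthetic_config(n_regions = 3, group_sizes = c(2, 2),
                     stimulus_correlation = s),
    "positive semidefinite.*eigenvalue")
})

test_that("subject synthesis follows the weight/noise model", {
  cfg <- synthetic_config(n_regions = 3, n_timepoints = 20000,
                          stimulus_correlation = diag(3), smoothness = 0,
                          group_sizes = c(2, 2), seed = 1)
  set.seed(21)
  lat <- sample_latent_stimulus(cfg)

  # zero weights: pure noise, uncorrelated with the latent
  x0 <- synthesize_subject(lat, rep(0, 3), noise_sd = 1)
  expect_lt(abs(cor(x0[, 1], lat[, 1])), 0.03)

  # noise-free limit: output approximately equals the latent
  x1 <- synthesize_subject(lat, rep(1, 3), noise_sd = 1e-8)
  expect_lt(max(abs(x1 - lat)), 1e-6)

  # attenuation: corr(x_r, latent_r) = w / sqrt(w^2 + sigma^2)
  x2 <- synthesize_subject(lat, rep(0.8, 3), noise_sd = 0.6)
  expect_lt(abs(cor(x2[, 1], lat[, 1]) - 0.8 / sqrt(0.64 + 0.36)), 0.03)

  expect_error(synthesize_subject(lat, rep(1, 5), 1), "regions")
})

test_that("expected pairwise ISFC matches the closed form", {
  # noise-free limit: rho converges to the stimulus correlation
  s <- diag(6); s[1, 2] <- s[2, 1] <- 0.4
  cfg <- synthetic_config(n_regions = 6, stimulus_correlation = s,
                          weights = list(rep(1, 6), rep(1, 6)),
                          noise_sd = 1e-9, group_sizes = c(2, 2))
  expect_lt(max(abs(expected_pairwise_isfc(cfg, "neurotypical") - s)), 1e-6)

  # zero-weight region: its row and column vanish
  w <- rep(0.8, 6); w[3] <- 0
  cfg2 <- synthetic_config(n_regions = 6, stimulus_correlation = s,
                           weights = list(w, w), group_sizes = c(2, 2))
  rho <- expected_pairwise_isfc(cfg2, "autism")
  expect_true(all(rho[3, ] == 0) && all(rho[, 3] == 0))

  # hand evaluation: w_i = w_j = 0.8, Sigma = 0.5, sigma = 0.6 -> 0.32
  s3 <- diag(2); s3[1, 2] <- s3[2, 1] <- 0.5
  cfg3 <- synthetic_config(n_regions = 2, stimulus_correlation = s3,
                           weights = list(c(0.8, 0.8), c(0.8, 0.8)),
                           noise_sd = 0.6, group_sizes = c(2, 2))
  expect_equal(expected_pairwise_isfc(cfg3, "neurotypical")[1, 2],
               0.64 * 0.5 / sqrt(1 * 1), tolerance = 1e-12)
  expect_equal(expected_pairwise_isfc(cfg3, "neurotypical")[1, 2], 0.32,
               tolerance = 1e-12)
})

test_that("build_dataset assembles subjects, truth and planted pairs", {
  cfg <- synthetic_config(n_regions = 8, n_timepoints = 50,
                          group_sizes = c(10, 9), seed = 3)
  ds <- build_dataset(cfg)
  expect_length(ds$subjects, 19)
  expect_identical(table(vapply(ds$subjects, `[[`, "", "group")),
                   table(rep(cfg$group_labels, c(10, 9))))
  expect_true(all(vapply(ds$subjects, function(s)
    identical(dim(s$data), c(50L, 8L)), logical(1))))

  # truth matrices are symmetric and bounded
  for (g in cfg$group_labels) {
    tr <- ds$truth_expected_isfc[[g]]
    expect_lt(max(abs(tr - t(tr))), 1e-12)
    expect_true(all(abs(tr) <= 1))
  }

  # equal weights: no planted pairs
  ds0 <- build_dataset(null_config(seed = 4, n_regions = 8,
                                   n_timepoints = 50, group_sizes = c(3, 3)))
  expect_identical(nrow(ds0$planted_pairs), 0L)

  # planted pairs are exactly those touching a weight-difference region
  # with a nonzero stimulus-correlation entry (enumerated from the formula)
  s <- diag(10); s[1:6, 1:6] <- 0.5; diag(s) <- 1
  w_nt <- rep(0.7, 10); w_nt[1:5] <- 0.9
  w_aut <- rep(0.7, 10); w_aut[1:5] <- 0.3
  cfg2 <- synthetic_config(n_regions = 10, n_timepoints = 50,
                           stimulus_correlation = s,
                           weights = list(w_nt, w_aut),
                           group_sizes = c(3, 3), seed = 5)
  ds2 <- build_dataset(cfg2)
  expected_pairs <- do.call(rbind, lapply(1:9, function(i)
    data.frame(i = i, j = (i + 1):10)))
  touches <- (expected_pairs$i <= 5 | expected_pairs$j <= 5) &
    (s[cbind(expected_pairs$i, expected_pairs$j)] != 0)
  want <- expected_pairs[touches, c("i", "j"), drop = FALSE]
  rownames(want) <- NULL
  expect_identical(ds2$planted_pairs[c("i", "j")], want)
  expect_true(all(ds2$planted_pairs$direction == 1))
})

test_that("dataset generation is byte-deterministic in the seed", {
  cfg <- synthetic_config(n_regions = 5, n_timepoints = 60,
                          group_sizes = c(3, 3), seed = 77)
  expect_identical(build_dataset(cfg), build_dataset(cfg))
  # and a different seed changes the data
  cfg2 <- synthetic_config(n_regions = 5, n_timepoints = 60,
                           group_sizes = c(3, 3), seed = 78)
  expect_false(identical(build_dataset(cfg)$subjects[[1]]$data,
                         build_dataset(cfg2)$subjects[[1]]$data))
})

test_that("simulated motion hits its mean-FD targets and mover counts", {
  cfg <- synthetic_config(n_regions = 4, n_timepoints = 300,
                          group_sizes = c(5, 5),
                          motion_mean_fd = c(0.2, 0.3),
                          high_mover_fraction = 0.2, seed = 9)
  set.seed(31)
  conf <- sample_motion_confounds(cfg)
  mfd <- vapply(conf, function(cf) mean(cf$framewise_displacement), numeric(1))
  expect_identical(sum(mfd > 0.5), 2L)  # exactly 20% of 10 subjects

  # non-movers sit exactly on their group's target (closed-form rescaling)
  groups <- rep(cfg$group_labels, times = cfg$group_sizes)
  ok <- mfd <= 0.5
  expect_equal(mfd[ok], cfg$motion_mean_fd[groups[ok]],
               tolerance = 1e-10, ignore_attr = TRUE)

  # with no high movers, nobody crosses the exclusion threshold
  cfg0 <- synthetic_config(n_regions = 4, n_timepoints = 300,
                           group_sizes = c(5, 5), high_mover_fraction = 0,
                           seed = 10)
  set.seed(32)
  conf0 <- sample_motion_confounds(cfg0)
  expect_true(all(vapply(conf0, function(cf)
    mean(cf$framewise_displacement), numeric(1)) <= 0.5))
})

test_that("motion is independent across subjects", {
  cfg <- synthetic_config(n_regions = 4, n_timepoints = 1000,
                          group_sizes = c(3, 3), high_mover_fraction = 0,
                          seed = 12)
  set.seed(33)
  conf <- sample_motion_confounds(cfg)
  fd <- vapply(conf, `[[`, numeric(1000), "framewise_displacement")
  cc <- cor(fd)
  expect_lt(max(abs(cc[upper.tri(cc)])), 3 / sqrt(1000))
})
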