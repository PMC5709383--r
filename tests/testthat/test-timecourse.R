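test_that("spherical masks enumerate the expected lattice voxels", {
  expect_equal(nrow(valuefmri:::sphere_offsets(0)), 1)
  expect_equal(nrow(valuefmri:::sphere_offsets(2)), 33)
  expect_equal(nrow(valuefmri:::sphere_offsets(1)), 7)
})

test_that("ROI extraction averages in-sphere voxels", {
  tr <- make_random_value_trials(6, seed = 61)
  g <- generate_linear_grid(tr, dim = c(9, 9, 9), center = c(5, 5, 5),
                            noise = NULL, seed = 62)
  # radius 0: exactly the center voxel's series
  s0 <- extract_roi(g, roi_mask(c(5, 5, 5), radius = 0))
  expect_equal(s0$values, g$data[5, 5, 5, ])
  # uniform field: extracted series equals any single voxel
  gu <- g
  gu$data <- array(rep(g$data[5, 5, 5, ], each = 9 * 9 * 9),
                   c(9, 9, 9, dim(g$data)[4]))
  s2 <- extract_roi(gu, roi_mask(c(5, 5, 5), radius = 2))
  expect_equal(s2$values, g$data[5, 5, 5, ], tolerance = 1e-12)
  expect_error(extract_roi(g, roi_mask(c(1, 1, 1), radius = 2)), "beyond")
})

test_that("epoching interpolates exactly on linear signals and TR-aligned events", {
  tr <- 2.28
  n <- 100
  ramp <- bold_series(3 + 0.5 * (0:(n - 1)) * tr, tr)
  ep <- epoch_upsample(ramp, events = c(50, 100), window = c(-2, 14),
                       step = 0.25)
  # linear functions are fixed points of linear interpolation
  for (i in 1:2) {
    expect_equal(ep$mat[i, ], 3 + 0.5 * (c(50, 100)[i] + ep$time),
                 tolerance = 1e-10)
  }
  # events whose window leaves the recording are dropped and reported
  ep2 <- epoch_upsample(ramp, events = c(1, 50), window = c(-2, 14))
  expect_equal(ep2$kept, 2L)
  expect_equal(ep2$dropped, 1L)

  # a series that is exactly the HRF response at each event reproduces the
  # TR-grid samples at TR-aligned epoch offsets
  h <- gamma_hrf()
  onset <- 20 * tr
  resp <- convolve_events(onset, 1, h, tr, n)
  ep3 <- epoch_upsample(resp, events = onset, window = c(0, 13.68),
                        step = tr / 2)
  aligned <- seq(1, length(ep3$time), by = 2)  # offsets that are TR multiples
  expect_equal(ep3$mat[1, aligned],
               resp$values[20 + seq_along(aligned)], tolerance = 1e-10)
})

test_that("jittered events still localize the mean epoch peak at the HRF peak", {
  set.seed(63)
  h <- gamma_hrf()
  tr <- 2.28
  onsets <- cumsum(runif(30, 18, 22))  # jittered relative to the TR grid
  n_vol <- ceiling((max(onsets) + 16) / tr) + 1
  series <- convolve_events(onsets, 1, h, tr, n_vol)
  ep <- epoch_upsample(series, onsets, window = c(-2, 14), step = 0.25)
  peak_t <- ep$time[which.max(colMeans(ep$mat))]
  hrf_peak <- h$times[which.max(h$kernel)]
  expect_lt(abs(peak_t - hrf_peak), 0.25 + tr / 2)
})

test_that("per-timepoint regression recovers a planted negative value effect", {
  set.seed(64)
  h <- gamma_hrf()
  tr_s <- 2.28
  n_trials <- 60
  onsets <- cumsum(runif(n_trials, 16, 20))
  diff_z <- as.numeric(scale(runif(n_trials)))
  amps <- 1 - 1 * diff_z
  n_vol <- ceiling((max(onsets) + 16) / tr_s) + 1
  clean <- convolve_events(onsets, amps, h, tr_s, n_vol)
  noisy <- bold_series(clean$values + rnorm(n_vol, 0, 0.1), tr_s)
  ep <- epoch_upsample(noisy, onsets)
  tb <- timepoint_regression(ep, data.frame(diff_z = diff_z))
  b <- tb$betas[, "diff_z"]
  peak_idx <- which.max(abs(b))
  expect_lt(b[peak_idx], 0)
  expect_lt(abs(tb$time[peak_idx] - h$times[which.max(h$kernel)]), 2)

  # permuting the regressor labels centers the betas on zero
  peak_b <- vapply(1:300, function(i) {
    timepoint_regression(ep, data.frame(diff_z = sample(diff_z)))$betas[peak_idx, "diff_z"]
  }, numeric(1))
  expect_gt(stats::binom.test(sum(peak_b > 0), length(peak_b))$p.value, 0.001)
  expect_lt(abs(mean(peak_b)), 3 * stats::sd(peak_b) / sqrt(length(peak_b)) + 0.05)
})

test_that("correlated RT regressor does not destroy joint value recovery", {
  set.seed(65)
  h <- gamma_hrf()
  tr_s <- 2.28
  n_trials <- 80
  onsets <- cumsum(runif(n_trials, 16, 20))
  diff_z <- as.numeric(scale(rnorm(n_trials)))
  rt_z <- as.numeric(scale(0.5 * diff_z + sqrt(1 - 0.25) * rnorm(n_trials)))
  amps <- 1 - 0.8 * diff_z + 0.5 * rt_z
  n_vol <- ceiling((max(onsets) + 16) / tr_s) + 1
  clean <- convolve_events(onsets, amps, h, tr_s, n_vol)
  noisy <- bold_series(clean$values + rnorm(n_vol, 0, 0.02), tr_s)
  ep <- epoch_upsample(noisy, onsets)
  tb <- timepoint_regression(ep, data.frame(diff_z = diff_z, rt_z = rt_z))
  peak_idx <- which.max(abs(tb$betas[, "diff_z"]))
  z <- tb$betas[peak_idx, "diff_z"] / tb$se[peak_idx, "diff_z"]
  expect_lt(z, -2)  # diff effect survives the correlated covariate
})

test_that("identical sessions make every leave-one-out fold pick one peak", {
  curve <- c(0, 0.2, 0.9, 0.4, 0.1)
  mat <- rbind(curve, curve, curve, curve)
  res <- loo_peak_stat(mat)
  expect_equal(unique(res$indices), 3L)
  expect_error(loo_peak_stat(mat[1:2, ]), ">= 3")
})

test_that("leave-one-out reduces session-level selection bias", {
  # directly t-testing held-out session values is still anticonservative
  # (the sessions share their selection folds), but far less so than
  # selecting on the same data; calibrated inference lives at the group
  # level (loo_group_stat)
  set.seed(66)
  n_sim <- 300
  hit_loo <- hit_biased <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    mat <- matrix(rnorm(6 * 30), 6, 30)
    hit_loo[i] <- loo_peak_stat(mat)$p < 0.05
    hit_biased[i] <- loo_peak_stat(mat, fold = FALSE)$p < 0.05
  }
  expect_lt(mean(hit_loo), mean(hit_biased) - 0.1)
})

test_that("group-level LOO inference is calibrated; common-peak selection is not", {
  set.seed(660)
  n_sim <- 250
  hit_loo <- hit_circ <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    mats <- lapply(1:5, function(s) matrix(rnorm(5 * 25), 5, 25))
    hit_loo[i] <- loo_group_stat(mats)$p < 0.05
    hit_circ[i] <- loo_group_stat(mats, biased = TRUE)$p < 0.05
  }
  expect_lt(abs(mean(hit_loo) - 0.05), 0.04)
  expect_gt(mean(hit_circ), 0.08)
})

test_that("a planted negative effect yields a significantly negative LOO t", {
  set.seed(67)
  h <- gamma_hrf()
  curve <- -h$kernel[round(seq(1, 150, length.out = 40))] * 20
  mat <- matrix(rep(curve, each = 6), 6, 40) + matrix(rnorm(240, 0, 0.02), 6, 40)
  res <- loo_peak_stat(mat)
  expect_lt(res$t, 0)
  expect_lt(res$p, 0.05)
})

test_that("trial peaks use the requested window and feed the factorial ANOVA", {
  # degenerate window: peak equals the single sample
  ep <- structure(list(mat = matrix(1:8, 4, 2), time = c(2, 5),
                       kept = 1:4, dropped = integer(0)),
                  class = "epoched_timecourse")
  res <- trial_peak_analysis(ep, data.frame(chosen = c("HV", "HV", "CV", "CV"),
                                            unchosen = c("LV", "U", "LV", "U")),
                             window = c(2, 2))
  expect_equal(res$peaks, 1:4)
  expect_error(trial_peak_analysis(ep, data.frame(chosen = 1:4, unchosen = 1),
                                   window = c(20, 30)), "window")

  # planted negative chosen-value and positive unchosen-value effects order
  # the cells as expected: hardest cell (low chosen, high unchosen) peaks top
  set.seed(68)
  cells <- expand.grid(chosen = c("CV", "HV"), unchosen = c("UNREW", "LV"),
                       subject = 1:4, rep = 1:6)
  chosen_val <- ifelse(cells$chosen == "HV", 1, 0.7)
  unchosen_val <- ifelse(cells$unchosen == "LV", 0.4, 0)
  amp <- 1 - 0.8 * chosen_val + 0.8 * unchosen_val + rnorm(nrow(cells), 0, 0.05)
  ep2 <- structure(list(mat = matrix(amp, ncol = 1), time = 3,
                        kept = seq_len(nrow(cells)), dropped = integer(0)),
                   class = "epoched_timecourse")
  res2 <- trial_peak_analysis(ep2, cells[, c("chosen", "unchosen", "subject")],
                              window = c(3, 3))
  expect_gt(res2$cell_means[["CV vs LV"]], res2$cell_means[["HV vs UNREW"]])
  expect_gt(res2$cell_means[["HV vs LV"]], res2$cell_means[["HV vs UNREW"]])
  aov_tab <- res2$anova
  expect_true(all(c("chosen", "unchosen") %in% aov_tab$effect))
  expect_lt(aov_tab$p[aov_tab$effect == "chosen"], 0.05)
  expect_lt(aov_tab$p[aov_tab$effect == "unchosen"], 0.05)
})

test_that("flat-signal peak ANOVA p-values are uniform under the null", {
  set.seed(69)
  pvals <- vapply(1:200, function(i) {
    cells <- expand.grid(chosen = c("A", "B"), unchosen = c("C", "D"),
                         subject = 1:5)
    ep <- structure(list(mat = matrix(rnorm(nrow(cells) * 4), nrow(cells), 4),
                         time = c(1.5, 3, 4.5, 6),
                         kept = seq_len(nrow(cells)), dropped = integer(0)),
                    class = "epoched_timecourse")
    tab <- trial_peak_analysis(ep, cells)$anova
    tab$p[tab$effect == "chosen:unchosen"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
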