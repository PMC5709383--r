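full_condition_session <- function() {
  # two trials of each of the nine decision-type x choice cells, plus two
  # discarded trials, spaced so responses never overlap
  offered_1 <- c("HV", "LV", "CV", "HV", "HV", "LV", "HV", "HV", "CV",
                 "HV", "LV", "CV", "LV", "CV", "HV", "CV", "LV", "LV",
                 "HV", "CV")
  offered_2 <- c("blank", "blank", "blank", "blank", "UNREW", "UNREW",
                 "CV", "LV", "LV",
                 "blank", "blank", "blank", "blank", "UNREW", "UNREW",
                 "HV", "HV", "CV",
                 "blank", "UNREW")
  choice <- c("HV", "LV", "CV", "skip", "HV", "LV", "HV", "HV", "CV",
              "HV", "LV", "CV", "skip", "UNREW", "HV", "CV", "HV", "LV",
              "HV", "UNREW")
  trial_type <- ifelse(offered_2 == "blank", "single",
                       ifelse(offered_2 == "UNREW", "choice_cs_minus",
                              "choice_cs_plus"))
  make_trials(offered_1, offered_2, choice,
              v_chosen = runif(20, 0.2, 1), v_unchosen = runif(20, 0, 0.8),
              trial_type = trial_type)
}

test_that("parametric design has ten named columns with centered modulators", {
  set.seed(51)
  tr <- full_condition_session()
  vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                     unchosen = tr$v_unchosen)
  des <- build_glm2(tr, vals, tr = 2)  # TR divides the 40 s event spacing
  expect_equal(ncol(des$X), 10)
  expect_setequal(colnames(des$X),
                  c("cue_cs", "cue_cs_x_sum", "cue_cs_x_diff", "out_cs",
                    "cue_nocs", "out_nocs", "resp_left", "resp_right",
                    "resp_left_spike", "resp_right_spike"))
  # events 40 s apart: the centered modulator column is orthogonal to its
  # parent event column
  p <- des$X[, "cue_cs"]
  for (mod in c("cue_cs_x_sum", "cue_cs_x_diff")) {
    expect_lt(abs(sum(des$X[, mod] * p)), 1e-10)
  }
})

test_that("degenerate sessions drop the empty no-CS+ columns with a warning", {
  set.seed(52)
  tr <- make_trials(rep("HV", 6), rep("CV", 6), rep("HV", 6),
                    v_chosen = runif(6), v_unchosen = runif(6))
  vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                     unchosen = tr$v_unchosen)
  expect_warning(des <- build_glm2(tr, vals), "cue_nocs")
  expect_true(all(c("cue_nocs", "out_nocs") %in% des$dropped))
  expect_false("cue_nocs" %in% colnames(des$X))
})

test_that("condition design has 24 columns and separates cue from outcome", {
  set.seed(53)
  tr <- full_condition_session()
  des <- build_glm1(tr, discard = c(rep(FALSE, 18), TRUE, TRUE))
  expect_equal(ncol(des$X), 24)
  expect_length(des$dropped, 0)
  # cue and outcome regressors of the same condition are distinct columns
  # whose peak responses are separated by the outcome delay
  cue_peak <- which.max(des$X[, "cue_single_HV"])
  out_peak <- which.max(des$X[, "out_single_HV"])
  expect_gt(out_peak, cue_peak)

  # a session missing a condition drops it with a warning
  tr2 <- tr[tr$choice != "UNREW", ]
  expect_warning(des2 <- build_glm1(tr2), "csm_took_csminus")
  expect_lt(ncol(des2$X), 24)
})

test_that("noiseless forward-model betas are recovered exactly", {
  set.seed(54)
  tr <- make_random_value_trials(40, seed = 54)
  vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                     unchosen = tr$v_unchosen)
  h <- gamma_hrf()
  n_vol <- ceiling((max(tr$t_outcome) + 16) / 2.28) + 1
  bold <- generate_linear_roi(tr, list(decision = 2, diff = -1, sum = 0.3,
                                       outcome = 0.5),
                              h, noise = NULL, n_volumes = n_vol)
  des <- suppressWarnings(build_glm2(tr, vals, h, n_volumes = n_vol))
  fit <- fit_glm_session(bold, des)
  expect_equal(unname(fit$betas["cue_cs"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$betas["cue_cs_x_diff"]), -1, tolerance = 1e-8)
  expect_equal(unname(fit$betas["cue_cs_x_sum"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(fit$betas["out_cs"]), 0.5, tolerance = 1e-8)
})

test_that("OLS matches the normal-equations oracle on a toy design", {
  set.seed(55)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  y <- rnorm(10)
  des <- valuefmri:::design_matrix(X, unconvolved = character(0),
                                   dropped = character(0))
  fit <- fit_glm_session(bold_series(y, tr = 1), des, highpass = NULL)
  Xi <- cbind(X, 1)
  oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(unname(fit$betas[1:2]), unname(oracle[1:2, 1]),
               tolerance = 1e-10)
})

test_that("high-pass filtering removes a 200 s cosine almost completely", {
  tr <- 2.28
  n <- 200
  t_s <- (0:(n - 1)) * tr
  slow <- cos(2 * pi * t_s / 200 + 0.7)
  filtered <- highpass_filter(slow, tr, cutoff = 100)
  expect_lt(max(abs(filtered)), 0.01)  # < 1% of unit amplitude
  # a fast component passes through nearly unchanged
  fast <- sin(2 * pi * t_s / 20)
  expect_gt(stats::sd(highpass_filter(fast, tr, 100)) / stats::sd(fast), 0.95)
})

test_that("contrast t-statistics are calibrated under the null", {
  set.seed(56)
  tr <- make_random_value_trials(40, seed = 56)
  vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                     unchosen = tr$v_unchosen)
  h <- gamma_hrf()
  n_vol <- ceiling((max(tr$t_outcome) + 16) / 2.28) + 1
  des <- suppressWarnings(build_glm2(tr, vals, h, n_volumes = n_vol))
  hits <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    bold <- bold_series(rnorm(n_vol), 2.28)
    fit <- fit_glm_session(bold, des)
    hits <- hits + (contrast(fit, c(cue_cs_x_diff = 1))$p < 0.05)
  }
  expect_lt(abs(hits / n_sim - 0.05), 0.025)
})

test_that("fixed effects and the group test behave as documented", {
  fe <- fixed_effects(c(1, 3), c(2, 2))
  expect_equal(fe$effect, 2)   # equal variances -> simple mean
  expect_equal(fe$variance, 1)
  one <- fixed_effects(5, 4)
  expect_equal(one$effect, 5)
  expect_equal(one$variance, 4)
  fe2 <- fixed_effects(c(0, 1), c(1, 3))
  expect_equal(fe2$effect, (0 / 1 + 1 / 3) / (1 + 1 / 3))

  set.seed(57)
  # planted negative effect, 4 subjects whose fixed-effects estimates are
  # well separated from zero: the group test detects it reliably
  detect <- vapply(1:200, function(i) {
    eff <- rnorm(4, mean = -3, sd = 1)
    g <- group_ttest(eff)
    g$p < 0.05 && g$t < 0
  }, logical(1))
  # power.t.test(n = 4, delta = 3, type = "one.sample") ~ 0.97
  expect_gt(mean(detect), 0.85)

  # null: p-values uniform
  set.seed(58)
  pvals <- vapply(1:500, function(i) group_ttest(rnorm(6))$p, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(group_ttest(1), ">= 2")
})

test_that("signed and absolute value-difference modulators separate cleanly", {
  set.seed(59)
  tr <- make_random_value_trials(60, seed = 59)
  h <- gamma_hrf()
  vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                     unchosen = tr$v_unchosen)
  d <- vals$chosen - vals$unchosen
  n_vol <- ceiling((max(tr$t_outcome) + 16) / 2.28) + 1
  zs <- function(x) (x - mean(x)) / sd(x)

  # planted signed effect only; both modulators fitted jointly
  amp <- 1 + 0.8 * zs(d)
  bold <- convolve_events(tr$t_cue, amp, h, 2.28, n_vol)
  res <- signed_vs_absolute(tr, vals, bold, h)
  expect_lt(abs(res$regressor_cor), 0.9)
  expect_equal(res$beta_signed, 0.8, tolerance = 1e-6)
  expect_equal(res$beta_abs, 0, tolerance = 1e-6)

  # collinear case refuses with a diagnostic
  tr_pos <- tr
  tr_pos$v_chosen <- tr$v_unchosen + runif(60, 0.1, 0.5)  # all diffs positive
  vals_pos <- data.frame(trial = tr$trial, chosen = tr_pos$v_chosen,
                         unchosen = tr_pos$v_unchosen)
  expect_error(signed_vs_absolute(tr_pos, vals_pos, bold, h), "collinear")
})
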