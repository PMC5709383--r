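test_that("chance-level test handles ceiling, symmetry and degeneracy", {
  deg <- test_vs_chance(c(60, 60, 60, 60))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))

  sym <- test_vs_chance(c(40, 60, 45, 55))
  expect_equal(sym$t, 0, tolerance = 1e-12)

  # near-ceiling synthetic agents: highly significant vs 50%
  set.seed(71)
  pct <- vapply(1:4, function(s) {
    tr <- generate_lessismore_session(lessismore_config(seed = 700 + s),
                                      subjective_agent(temperature = 0.15))
    ch <- tr$trial_type == "choice_cs_plus"
    100 * mean(tr$v_chosen[ch] >= tr$v_unchosen[ch])
  }, numeric(1))
  res <- test_vs_chance(pct)
  expect_lt(res$p, 0.001)
  expect_gt(res$mean, 80)
  expect_error(test_vs_chance(50), ">= 2")
  expect_error(test_vs_chance(c(120, 30)), "0, 100")
})

test_that("RT regression is exact without noise and recovers planted slopes", {
  set.seed(72)
  m <- rt_model(intercept_ms = 1000, b_sum = -100, b_diff = -50, noise_sd = 0)
  vc <- runif(40, 0.2, 1)
  vu <- runif(40, 0, 0.8)
  tr <- data.frame(subject = 1, session = 1, rt_ms = simulate_rt(m, vc, vu),
                   v_chosen = vc, v_unchosen = vu)
  res <- rt_regression(tr)
  expect_equal(res$subject_betas$b_sum, -100, tolerance = 1e-8)
  expect_equal(res$subject_betas$b_diff, -50, tolerance = 1e-8)
  expect_null(res$group_sum)  # one subject cannot support a group test

  # 4 subjects x 4 sessions x 30 choice trials with noise: both group
  # effects negative and significant
  m2 <- rt_model(noise_sd = 60)
  rows <- list()
  for (s in 1:4) for (k in 1:4) {
    vc <- runif(30, 0.2, 1)
    vu <- runif(30, 0, 0.8)
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, session = k, rt_ms = simulate_rt(m2, vc, vu),
      v_chosen = vc, v_unchosen = vu)
  }
  res2 <- rt_regression(do.call(rbind, rows))
  expect_lt(res2$group_sum$t, 0)
  expect_lt(res2$group_sum$p, 0.05)
  expect_lt(res2$group_diff$t, 0)
  expect_lt(res2$group_diff$p, 0.05)
})

test_that("null RT slopes give uniform group p-values", {
  set.seed(73)
  m0 <- rt_model(b_sum = 0, b_diff = 0, noise_sd = 60)
  pvals <- vapply(1:200, function(i) {
    rows <- list()
    for (s in 1:4) for (k in 1:3) {
      vc <- runif(25, 0.2, 1)
      vu <- runif(25, 0, 0.8)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, session = k, rt_ms = simulate_rt(m0, vc, vu),
        v_chosen = vc, v_unchosen = vu)
    }
    rt_regression(do.call(rbind, rows))$group_diff$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("repeated-measures ANOVA matches a hand sums-of-squares oracle", {
  # two within conditions, four subjects: classic paired design where
  # F = t^2 and every SS is computable by hand
  d <- data.frame(subject = rep(1:4, each = 2),
                  cond = rep(c("a", "b"), 4),
                  y = c(5, 7, 6, 9, 4, 6, 7, 11))
  res <- rm_anova(d, dv = "y", within = "cond")
  y <- matrix(d$y, ncol = 2, byrow = TRUE)
  diffs <- y[, 2] - y[, 1]
  t_paired <- mean(diffs) / (sd(diffs) / sqrt(4))
  expect_equal(res$F[res$effect == "cond"], t_paired^2, tolerance = 1e-8)
  expect_equal(res$df1[res$effect == "cond"], 1)
  expect_equal(res$df2[res$effect == "cond"], 3)

  # hand SS decomposition for the condition stratum
  grand <- mean(d$y)
  ss_cond <- 4 * sum((tapply(d$y, d$cond, mean) - grand)^2)
  subj_m <- tapply(d$y, d$subject, mean)
  ss_subj <- 2 * sum((subj_m - grand)^2)
  ss_tot <- sum((d$y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  expect_equal(res$F[res$effect == "cond"], (ss_cond / 1) / (ss_err / 3),
               tolerance = 1e-8)
})

test_that("a null condition effect gives F = 0 and imbalance errors", {
  # per-subject deviations that cancel exactly across the condition means:
  # zero condition sum of squares against nonzero error
  delta <- c(1, -1, 2, -2, 0)
  d <- data.frame(subject = rep(1:5, each = 2),
                  cond = rep(c("a", "b"), 5),
                  y = rep(c(4, 7, 3, 6, 5), each = 2) + c(rbind(0, delta)))
  res <- rm_anova(d, dv = "y", within = "cond")
  expect_equal(res$F[res$effect == "cond"], 0, tolerance = 1e-10)

  expect_error(rm_anova(d[-1, ], dv = "y", within = "cond"), "balanced")
  expect_error(rm_anova(d, dv = "z", within = "cond"), "missing column")
})

test_that("square-root transform is applied before the decomposition", {
  d <- data.frame(subject = rep(1:4, each = 2),
                  cond = rep(c("a", "b"), 4),
                  y = c(1, 4, 1, 9, 4, 16, 1, 4))
  res_sqrt <- rm_anova(d, dv = "y", within = "cond", transform = "sqrt")
  d2 <- d
  d2$y <- sqrt(d$y)
  res_manual <- rm_anova(d2, dv = "y", within = "cond")
  expect_equal(res_sqrt$F, res_manual$F, tolerance = 1e-10)
  d$y[1] <- -1
  expect_error(rm_anova(d, dv = "y", within = "cond", transform = "sqrt"),
               "non-negative")
})

test_that("lesion-like indifference produces the group x decision interaction", {
  set.seed(74)
  # control agents average the compound's components (cv_bias 1); lesion
  # agents sit halfway to summation and so lose the HV-over-CV preference
  simulate_pct <- function(cv_bias, decision, n = 20, temp = 0.15) {
    ag <- subjective_agent(cv_bias = cv_bias, temperature = temp)
    v <- switch(decision,
                hv_cv = c(ag$values["HV"], ag$values["CV"]),
                cv_lv = c(ag$values["CV"], ag$values["LV"]),
                hv_lv = c(ag$values["HV"], ag$values["LV"]))
    p_first <- 1 / (1 + exp(-(v[1] - v[2]) / temp))  # % taking the CS+
    100 * mean(rbinom(n, 1, p_first))                # designated as better
  }
  detect <- vapply(1:200, function(i) {
    rows <- list()
    for (s in 1:8) {
      grp <- if (s <= 4) "control" else "lesion"
      bias <- if (grp == "control") 1 else 0.5
      for (day in 1:4) for (dec in c("hv_cv", "cv_lv", "hv_lv")) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, group = grp, day = day, decision = dec,
          pct = simulate_pct(bias, dec))
      }
    }
    tab <- suppressWarnings(
      rm_anova(do.call(rbind, rows), dv = "pct",
               within = c("day", "decision"), between = "group"))
    tab$p[tab$effect == "group:decision"] < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.8)
})

test_that("anova total SS equals the sum of the component SS", {
  set.seed(75)
  d <- expand.grid(subject = 1:6, a = c("x", "y"), b = c("p", "q"))
  d$y <- rnorm(nrow(d))
  res <- rm_anova(d, dv = "y", within = c("a", "b"))
  fit <- stats::aov(y ~ a * b + Error(subject / (a * b)), data = d)
  ss <- 0
  for (stratum in summary(fit)) {
    tab <- as.data.frame(if (is.list(stratum)) stratum[[1]] else stratum)
    ss <- ss + sum(tab$`Sum Sq`)
  }
  expect_equal(ss, sum((d$y - mean(d$y))^2), tolerance = 1e-8)
})
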