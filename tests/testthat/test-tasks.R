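test_that("trial-type allocation is deterministic and exact", {
  cfg <- lessismore_config(seed = 1)
  tr <- generate_lessismore_session(cfg, subjective_agent())
  counts <- table(tr$trial_type)
  expect_equal(unname(counts[["single"]]), 90)
  expect_equal(unname(counts[["choice_cs_minus"]]) +
                 unname(counts[["choice_cs_plus"]]), 30)
  expect_equal(unname(counts[["choice_cs_minus"]]), 15)

  # non-integral products follow the documented rounding rule:
  # single count rounded to nearest, remainder to choice trials
  cfg2 <- lessismore_config(n_trials = 121, p_single = 0.75, seed = 2)
  tr2 <- generate_lessismore_session(cfg2, subjective_agent())
  expect_equal(sum(tr2$trial_type == "single"), round(121 * 0.75))
  expect_equal(nrow(tr2), 121)
})

test_that("greedy-limit agent always takes the higher-valued option", {
  ag <- subjective_agent(temperature = 1e-6)
  cfg <- lessismore_config(seed = 3)
  tr <- generate_lessismore_session(cfg, ag)
  hc <- tr$trial_type == "choice_cs_plus" &
    ((tr$offered_1 == "HV" & tr$offered_2 == "CV") |
       (tr$offered_1 == "CV" & tr$offered_2 == "HV"))
  expect_true(any(hc))
  expect_true(all(tr$choice[hc] == "HV"))
})

test_that("empirical choice rates match the analytic softmax oracle", {
  ag <- subjective_agent(v_hv = 1, v_lv = 0.4, cv_bias = 1, temperature = 0.15)
  expect_equal(unname(ag$values["CV"]), 0.7)
  cfg <- lessismore_config(n_trials = 10000, p_single = 0,
                           p_csminus_of_choice = 0, seed = 4)
  tr <- generate_lessismore_session(cfg, ag)
  # direct enumeration oracle: two-option softmax probability per pair
  oracle <- function(v1, v2) 1 / (1 + exp(-(v1 - v2) / ag$temperature))
  for (pair in list(c("HV", "CV"), c("HV", "LV"), c("CV", "LV"))) {
    sel <- (tr$offered_1 == pair[1] & tr$offered_2 == pair[2]) |
      (tr$offered_1 == pair[2] & tr$offered_2 == pair[1])
    emp <- mean(tr$choice[sel] == pair[1])
    exp_p <- oracle(ag$values[pair[1]], ag$values[pair[2]])
    expect_lt(abs(emp - exp_p), 0.02)
  }
})

test_that("reaction-time model reproduces hand arithmetic and is recoverable", {
  m0 <- rt_model(intercept_ms = 1000, b_sum = -100, b_diff = -50,
                 noise_sd = 0)
  expect_equal(simulate_rt(m0, 1, 0.4), 1000 - 140 - 30)
  mnull <- rt_model(intercept_ms = 800, b_sum = 0, b_diff = 0, noise_sd = 0)
  expect_equal(simulate_rt(mnull, c(0, 1, 5), c(2, 0, -1)), rep(800, 3))

  set.seed(5)
  m <- rt_model(noise_sd = 50)
  vc <- runif(10000, 0.2, 1)
  vu <- runif(10000, 0, 0.8)
  rt <- simulate_rt(m, vc, vu)
  fit <- lm(rt ~ I(vc + vu) + I(vc - vu))
  ci <- confint(fit)
  expect_gt(m$b_sum, ci["I(vc + vu)", 1])
  expect_lt(m$b_sum, ci["I(vc + vu)", 2])
  expect_gt(m$b_diff, ci["I(vc - vu)", 1])
  expect_lt(m$b_diff, ci["I(vc - vu)", 2])
  expect_true(all(rt >= m$floor_ms))
})

test_that("reversal generator draws 2 of 3, stays in bounds, updates by RW", {
  cfg <- reversal_config(n_trials = 1, seed = 6)
  one <- generate_reversal_session(cfg, rl_params(0.3, 0.2))
  expect_equal(nrow(one), 1)
  expect_length(unique(c(one$offered_1, one$offered_2)), 2)

  cfg <- reversal_config(n_trials = 300, seed = 7)
  tr <- generate_reversal_session(cfg, rl_params(0.3, 0.2))
  expect_true(all(tr$offered_1 != tr$offered_2))
  expect_true(all(tr$choice == tr$offered_1 | tr$choice == tr$offered_2))
  p <- as.matrix(tr[, c("p_1", "p_2", "p_3")])
  expect_true(all(p >= 0.1 & p <= 0.9))
  # value trace obeys the delta rule with the generator's alpha
  trace <- attr(tr, "value_trace")
  for (t in 1:(nrow(tr) - 1)) {
    expected <- trace[t, ]
    expected[tr$choice[t]] <- expected[tr$choice[t]] +
      0.3 * (tr$reward[t] - expected[tr$choice[t]])
    expect_equal(trace[t + 1, ], expected, tolerance = 1e-12)
  }
})

test_that("greedy agent converges on the best stimulus when walks are frozen", {
  # well-separated frozen probabilities: a near-greedy learner with a
  # modest learning rate (so value estimates fluctuate little around their
  # asymptotes) takes the better offered stimulus almost always
  cfg <- reversal_config(n_trials = 600, walk_step_sd = 0,
                         walk_start = c(0.85, 0.5, 0.15),
                         walk_bounds = c(0.05, 0.95), seed = 8)
  tr <- generate_reversal_session(cfg, rl_params(0.1, 0.01))
  p <- as.matrix(tr[, c("p_1", "p_2", "p_3")])
  post <- 101:600  # after burn-in
  best_avail <- ifelse(p[cbind(post, tr$offered_1[post])] >=
                         p[cbind(post, tr$offered_2[post])],
                       tr$offered_1[post], tr$offered_2[post])
  expect_gt(mean(tr$choice[post] == best_avail), 0.95)
})

test_that("session generators are bit-reproducible and times increase", {
  a <- generate_lessismore_session(lessismore_config(seed = 9),
                                   subjective_agent())
  b <- generate_lessismore_session(lessismore_config(seed = 9),
                                   subjective_agent())
  expect_identical(a, b)
  expect_strictly_increasing(c(rbind(a$t_cue, a$t_response, a$t_outcome)))

  r1 <- generate_reversal_session(reversal_config(seed = 10), rl_params(0.3, 0.2))
  r2 <- generate_reversal_session(reversal_config(seed = 10), rl_params(0.3, 0.2))
  expect_identical(r1, r2)
  expect_strictly_increasing(c(rbind(r1$t_cue, r1$t_response, r1$t_outcome)))
})

test_that("invalid configurations are rejected", {
  expect_error(lessismore_config(p_single = 1.2), "p_single")
  expect_error(lessismore_config(n_trials = 0), "n_trials")
  expect_error(lessismore_config(iti_range = c(7, 5)), "iti_range")
  expect_error(subjective_agent(temperature = 0), "temperature")
  expect_error(subjective_agent(cv_bias = 2), "cv_bias")
})
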