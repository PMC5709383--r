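#' Configuration for the single/choice ("less-is-more") session
#'
#' One session mixes single-option trials (one CS+ shown; the animal may take
#' it or skip by touching the blank side) with choice trials (two stimuli).
#' Choice trials split into CS+ vs CS- pairs and CS+ vs CS+ pairs; the split
#' proportion is configurable because the two subsets must jointly fill the
#' `1 - p_single` share of the session.
#'
#' @param n_trials Number of trials (default 120).
#' @param p_single Proportion of single-option trials (default 0.75, i.e.
#'   90 of 120 trials).
#' @param p_csminus_of_choice Proportion of *choice* trials that pit a CS+
#'   against a CS- (default 0.5; the remainder are CS+ vs CS+ pairs).
#' @param iti_range Uniform inter-trial-interval bounds in seconds.
#' @param outcome_delay_mean,outcome_delay_jitter Response-to-outcome delay:
#'   uniform on mean +/- jitter, in seconds.
#' @param outcome_duration Outcome phase duration in seconds.
#' @param reward_amounts Named objective reward amounts delivered per chosen
#'   option (CV is objectively HV + LV).
#' @param seed Optional integer seed; with a fixed seed the generator is
#'   bit-reproducible.
#' @return An object of class `lessismore_config`.
#' @export
lessismore_config <- function(n_trials = 120, p_single = 0.75,
                              p_csminus_of_choice = 0.5,
                              iti_range = c(5, 7),
                              outcome_delay_mean = 4,
                              outcome_delay_jitter = 0.5,
                              outcome_duration = 3,
                              reward_amounts = c(HV = 1, LV = 0.4, CV = 1.4,
                                                 UNREW = 0, blank = 0),
                              seed = NULL) {
  if (n_trials <= 0) stop("`n_trials` must be positive", call. = FALSE)
  if (p_single < 0 || p_single > 1) {
    stop("`p_single` must lie in [0, 1]", call. = FALSE)
  }
  if (p_csminus_of_choice < 0 || p_csminus_of_choice > 1) {
    stop("`p_csminus_of_choice` must lie in [0, 1]", call. = FALSE)
  }
  if (length(iti_range) != 2 || iti_range[1] > iti_range[2]) {
    stop("`iti_range` must be c(low, high) with low <= high", call. = FALSE)
  }
  needed <- c("HV", "LV", "CV", "UNREW", "blank")
  if (!all(needed %in% names(reward_amounts))) {
    stop("`reward_amounts` must name ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), p_single = p_single,
         p_csminus_of_choice = p_csminus_of_choice,
         iti_range = iti_range,
         outcome_delay_mean = outcome_delay_mean,
         outcome_delay_jitter = outcome_delay_jitter,
         outcome_duration = outcome_duration,
         reward_amounts = reward_amounts,
         seed = seed),
    class = "lessismore_config"
  )
}

# deterministic allocation of trial-type counts: single count rounded to
# nearest integer, remainder to choice trials; CS- subset rounded likewise
lessismore_counts <- function(config) {
  n_single <- round(config$n_trials * config$p_single)
  n_choice <- config$n_trials - n_single
  n_csm <- round(n_choice * config$p_csminus_of_choice)
  list(n_single = n_single, n_choice = n_choice,
       n_csm = n_csm, n_csp = n_choice - n_csm)
}

# cycle x to length n (balanced condition allocation before shuffling)
cycle_to <- function(x, n) rep(x, length.out = n)

#' Generate one session of the single/choice task
#'
#' Trial types are allocated deterministically (counts are exact whenever
#' `n_trials * p_single` is integral) and then shuffled. On every trial the
#' agent chooses by softmax over the values of the available actions: on
#' single-option trials between the offered CS+ and skipping (the blank
#' side), on choice trials between the two stimuli. Reaction times come from
#' the linear `rt_model`; cue, response and outcome times accumulate the
#' jittered ITIs and delays, so event times strictly increase.
#'
#' @param config A [lessismore_config()].
#' @param agent A [subjective_agent()].
#' @param rt A [rt_model()].
#' @return A `data.frame` with one row per trial: `trial`, `trial_type`
#'   (`"single"`, `"choice_cs_minus"`, `"choice_cs_plus"`), `offered_1`,
#'   `offered_2` (`"blank"` on single-option trials), `side_1` (screen side
#'   of `offered_1`), `choice` (option label or `"skip"`), `rt_ms`,
#'   `outcome` (objective reward amount), `v_chosen`, `v_unchosen` (agent
#'   subjective values; the unchosen value of a taken single option is the
#'   skip value), and event times `t_cue`, `t_response`, `t_outcome` in
#'   seconds from session start.
#' @export
generate_lessismore_session <- function(config, agent, rt = rt_model()) {
  stopifnot(inherits(config, "lessismore_config"),
            inherits(agent, "subjective_agent"),
            inherits(rt, "rt_model"))
  if (!all(is.finite(agent$values))) {
    stop("agent values must be finite", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cnt <- lessismore_counts(config)

  cs <- c("HV", "LV", "CV")
  single_opts <- cycle_to(cs, cnt$n_single)
  csm_opts <- cycle_to(cs, cnt$n_csm)
  csp_pairs <- cycle_to(list(c("HV", "CV"), c("HV", "LV"), c("CV", "LV")),
                        cnt$n_csp)

  offered_1 <- c(single_opts, csm_opts,
                 vapply(csp_pairs, `[`, character(1), 1))
  offered_2 <- c(rep("blank", cnt$n_single), rep("UNREW", cnt$n_csm),
                 vapply(csp_pairs, `[`, character(1), 2))
  trial_type <- rep(c("single", "choice_cs_minus", "choice_cs_plus"),
                    times = c(cnt$n_single, cnt$n_csm, cnt$n_csp))

  ord <- sample.int(config$n_trials)
  offered_1 <- offered_1[ord]
  offered_2 <- offered_2[ord]
  trial_type <- trial_type[ord]

  v1 <- agent$values[offered_1]
  v2 <- agent$values[offered_2]
  p1 <- 1 / (1 + exp(-(v1 - v2) / agent$temperature))
  take_first <- stats::runif(config$n_trials) < p1
  choice <- ifelse(take_first, offered_1, offered_2)
  choice[choice == "blank"] <- "skip"

  v_chosen <- ifelse(take_first, v1, v2)
  v_unchosen <- ifelse(take_first, v2, v1)
  rt_ms <- simulate_rt(rt, v_chosen, v_unchosen)

  amounts <- c(config$reward_amounts, skip = unname(config$reward_amounts["blank"]))
  outcome <- unname(amounts[choice])

  n <- config$n_trials
  iti <- stats::runif(n, config$iti_range[1], config$iti_range[2])
  delay <- stats::runif(n,
                        config$outcome_delay_mean - config$outcome_delay_jitter,
                        config$outcome_delay_mean + config$outcome_delay_jitter)
  t_cue <- numeric(n)
  t_cue[1] <- iti[1]
  t_response <- numeric(n)
  t_outcome <- numeric(n)
  for (i in seq_len(n)) {
    t_response[i] <- t_cue[i] + rt_ms[i] / 1000
    t_outcome[i] <- t_response[i] + delay[i]
    if (i < n) t_cue[i + 1] <- t_outcome[i] + config$outcome_duration + iti[i + 1]
  }

  out <- data.frame(
    trial = seq_len(n),
    trial_type = trial_type,
    offered_1 = offered_1,
    offered_2 = offered_2,
    side_1 = sample(c("left", "right"), n, replace = TRUE),
    choice = choice,
    rt_ms = rt_ms,
    outcome = outcome,
    v_chosen = unname(v_chosen),
    v_unchosen = unname(v_unchosen),
    t_cue = t_cue,
    t_response = t_response,
    t_outcome = t_outcome,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  attr(out, "agent") <- agent
  out
}

#' Configuration for the three-option probabilistic reversal session
#'
#' Each of `n_stimuli` stimuli carries a reward probability that drifts over
#' the session as a reflected Gaussian random walk; on every trial two of the
#' three stimuli are drawn uniformly without replacement for the agent to
#' choose between.
#'
#' @param n_trials Number of trials (default 200).
#' @param n_stimuli Number of stimuli (default 3).
#' @param walk_start_range Uniform bounds for each stimulus's starting
#'   reward probability.
#' @param walk_start Optional explicit vector of starting probabilities
#'   (length `n_stimuli`), overriding the random draw.
#' @param walk_step_sd Per-trial Gaussian step SD of the walk.
#' @param walk_bounds Reflection bounds keeping probabilities inside (0, 1).
#' @param iti_range Uniform ITI bounds in seconds.
#' @param outcome_duration Outcome phase duration in seconds.
#' @param rt_mean_ms,rt_sd_ms,rt_floor_ms Reaction-time draw (truncated
#'   Gaussian); this task has no value-dependent RT model.
#' @param seed Optional integer seed.
#' @return An object of class `reversal_config`.
#' @export
reversal_config <- function(n_trials = 200, n_stimuli = 3,
                            walk_start_range = c(0.2, 0.8),
                            walk_start = NULL,
                            walk_step_sd = 0.03,
                            walk_bounds = c(0.1, 0.9),
                            iti_range = c(5, 7),
                            outcome_duration = 1.5,
                            rt_mean_ms = 500, rt_sd_ms = 100,
                            rt_floor_ms = 250,
                            seed = NULL) {
  if (n_trials <= 0) stop("`n_trials` must be positive", call. = FALSE)
  if (n_stimuli < 2) stop("`n_stimuli` must be >= 2", call. = FALSE)
  stopifnot(walk_bounds[1] < walk_bounds[2],
            walk_bounds[1] >= 0, walk_bounds[2] <= 1,
            walk_step_sd >= 0)
  structure(
    list(n_trials = as.integer(n_trials), n_stimuli = as.integer(n_stimuli),
         walk_start_range = walk_start_range, walk_start = walk_start,
         walk_step_sd = walk_step_sd,
         walk_bounds = walk_bounds, iti_range = iti_range,
         outcome_duration = outcome_duration,
         rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
         rt_floor_ms = rt_floor_ms, seed = seed),
    class = "reversal_config"
  )
}

# reflect x into [lo, hi] (repeated folding handles large excursions)
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Simulate drifting reward probabilities
#'
#' Reflected Gaussian random walk per stimulus: starts drawn uniformly from
#' `walk_start_range`, steps N(0, `walk_step_sd`), reflected at
#' `walk_bounds` so every probability stays strictly inside \[0, 1\].
#'
#' @param config A [reversal_config()].
#' @return Matrix `n_trials x n_stimuli` of reward probabilities.
#' @export
simulate_reward_walk <- function(config) {
  stopifnot(inherits(config, "reversal_config"))
  n <- config$n_trials
  k <- config$n_stimuli
  p <- matrix(NA_real_, n, k)
  p[1, ] <- if (!is.null(config$walk_start)) {
    rep_len(config$walk_start, k)
  } else {
    stats::runif(k, config$walk_start_range[1], config$walk_start_range[2])
  }
  if (n > 1) {
    steps <- matrix(stats::rnorm((n - 1) * k, 0, config$walk_step_sd),
                    n - 1, k)
    for (t in 2:n) {
      p[t, ] <- reflect_into(p[t - 1, ] + steps[t - 1, ],
                             config$walk_bounds[1], config$walk_bounds[2])
    }
  }
  if (any(p < 0 | p > 1)) {
    stop("internal error: reward walk left [0, 1] despite reflection",
         call. = FALSE)
  }
  p
}

#' Generate one session of the three-option reversal task
#'
#' Two of the three stimuli are drawn uniformly without replacement per
#' trial; a Rescorla-Wagner agent chooses between them by softmax over its
#' current value estimates, the reward is Bernoulli in the drifting
#' probability of the chosen stimulus, and the agent's values are updated by
#' the delta rule.
#'
#' @param config A [reversal_config()].
#' @param params [rl_params()] of the simulated agent.
#' @param v0 Initial value estimate for every stimulus (default 0.5).
#' @return A `data.frame` with one row per trial: `trial`, `offered_1`,
#'   `offered_2` (stimulus indices), `choice`, `reward` (0/1), `v_chosen`,
#'   `v_unchosen` (agent values *before* the update), reward probabilities
#'   `p_1..p_k`, `rt_ms` and event times `t_cue`, `t_response`,
#'   `t_outcome`. The pre-choice value matrix is attached as attribute
#'   `"value_trace"`.
#' @export
generate_reversal_session <- function(config, params, v0 = 0.5) {
  stopifnot(inherits(config, "reversal_config"), inherits(params, "rl_params"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  k <- config$n_stimuli
  p <- simulate_reward_walk(config)

  V <- rep(v0, k)
  trace <- matrix(NA_real_, n, k)
  offered <- matrix(NA_integer_, n, 2)
  choice <- integer(n)
  reward <- integer(n)
  v_chosen <- numeric(n)
  v_unchosen <- numeric(n)
  for (t in seq_len(n)) {
    trace[t, ] <- V
    off <- sample.int(k, 2)
    offered[t, ] <- off
    pr <- softmax_probs(V, params$temp, offered = off)
    c_t <- off[1 + (stats::runif(1) >= pr[1])]
    choice[t] <- c_t
    reward[t] <- stats::rbinom(1, 1, p[t, c_t])
    v_chosen[t] <- V[c_t]
    v_unchosen[t] <- V[setdiff(off, c_t)]
    V <- rw_update(V, c_t, reward[t], params$alpha)
  }

  rt_ms <- pmax(stats::rnorm(n, config$rt_mean_ms, config$rt_sd_ms),
                config$rt_floor_ms)
  iti <- stats::runif(n, config$iti_range[1], config$iti_range[2])
  t_cue <- numeric(n)
  t_response <- numeric(n)
  t_outcome <- numeric(n)
  t_cue[1] <- iti[1]
  for (i in seq_len(n)) {
    t_response[i] <- t_cue[i] + rt_ms[i] / 1000
    t_outcome[i] <- t_response[i] + 0.2  # feedback follows the touch quickly
    if (i < n) t_cue[i + 1] <- t_outcome[i] + config$outcome_duration + iti[i + 1]
  }

  out <- data.frame(
    trial = seq_len(n),
    offered_1 = offered[, 1],
    offered_2 = offered[, 2],
    choice = choice,
    side_1 = sample(c("left", "right"), n, replace = TRUE),
    reward = reward,
    v_chosen = v_chosen,
    v_unchosen = v_unchosen,
    rt_ms = rt_ms,
    t_cue = t_cue,
    t_response = t_response,
    t_outcome = t_outcome,
    stringsAsFactors = FALSE
  )
  colnames(p) <- paste0("p_", seq_len(k))
  out <- cbind(out, p)
  attr(out, "config") <- config
  attr(out, "value_trace") <- trace
  out
}

#' Probability that the chosen stimulus is offered again on the next trial
#'
#' With 2 of 3 stimuli drawn uniformly without replacement, any designated
#' stimulus appears on the next trial with probability 2/3; this empirical
#' check is reported as a percentage.
#'
#' @param trials A reversal-session `data.frame` (or several stacked with
#'   distinct `session` values; re-offers are then computed within session).
#' @return Percentage of trials `t < N` whose chosen stimulus is among the
#'   two offered at `t + 1`.
#' @export
reoffer_rate <- function(trials) {
  stopifnot(all(c("offered_1", "offered_2", "choice") %in% names(trials)))
  grp <- if ("session" %in% names(trials)) trials$session else rep(1L, nrow(trials))
  hits <- 0L
  total <- 0L
  for (g in unique(grp)) {
    tr <- trials[grp == g, ]
    n <- nrow(tr)
    if (n < 2) next
    nxt <- 2:n
    hits <- hits + sum(tr$choice[nxt - 1] == tr$offered_1[nxt] |
                         tr$choice[nxt - 1] == tr$offered_2[nxt])
    total <- total + (n - 1)
  }
  if (total == 0) stop("need at least 2 trials", call. = FALSE)
  100 * hits / total
}
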