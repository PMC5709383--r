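# Hand-built single/choice-task trials with controllable structure: events
# spaced far apart so HRF responses never overlap unless asked for.
make_trials <- function(offered_1, offered_2, choice,
                        v_chosen, v_unchosen,
                        spacing = 40, rt_ms = 500, delay = 4,
                        trial_type = NULL, side_1 = NULL) {
  n <- length(offered_1)
  if (is.null(trial_type)) {
    trial_type <- ifelse(offered_2 == "blank", "single",
                         ifelse(offered_2 == "UNREW" | offered_1 == "UNREW",
                                "choice_cs_minus", "choice_cs_plus"))
  }
  if (is.null(side_1)) side_1 <- rep(c("left", "right"), length.out = n)
  t_cue <- spacing * seq_len(n)
  data.frame(
    trial = seq_len(n), trial_type = trial_type,
    offered_1 = offered_1, offered_2 = offered_2, side_1 = side_1,
    choice = choice, rt_ms = rep_len(rt_ms, n), outcome = 0,
    v_chosen = v_chosen, v_unchosen = v_unchosen,
    t_cue = t_cue, t_response = t_cue + rep_len(rt_ms, n) / 1000,
    t_outcome = t_cue + rep_len(rt_ms, n) / 1000 + delay,
    stringsAsFactors = FALSE
  )
}

# sessions with per-trial values drawn so the signed difference takes both
# signs (chosen value is not sorted above unchosen)
make_random_value_trials <- function(n, spacing = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_trials(offered_1 = rep("HV", n), offered_2 = rep("CV", n),
              choice = rep("HV", n),
              v_chosen = stats::runif(n), v_unchosen = stats::runif(n),
              spacing = spacing)
}

expect_strictly_increasing <- function(x) {
  expect_true(all(diff(x) > 0))
}
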