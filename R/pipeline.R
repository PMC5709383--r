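#' Split a top-level seed into per-stage seeds
#'
#' Deterministically expands one integer seed into `n` independent stage
#' seeds by seeding R's generator and sampling without replacement from
#' the 31-bit integer range.
#'
#' @param seed Top-level integer seed.
#' @param n Number of stage seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' Run configuration for an end-to-end simulated experiment
#'
#' Bundles the task, agent and generator settings plus explicit per-stage
#' seeds derived from one top-level seed. The configuration round-trips
#' through JSON unchanged.
#'
#' @param experiment `"lessismore"` or `"reversal"`.
#' @param n_subjects,n_sessions Simulated cohort size.
#' @param seed Top-level seed; stage seeds are derived with [split_seed()].
#' @param agent_args,task_args,glm_betas Named lists overriding the
#'   defaults of [subjective_agent()] / [rl_params()], the task config and
#'   the linear BOLD betas.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = c("lessismore", "reversal"),
                       n_subjects = 4, n_sessions = 4, seed = 1,
                       agent_args = list(), task_args = list(),
                       glm_betas = list(), out_dir = tempfile("valuefmri_")) {
  experiment <- match.arg(experiment)
  stage_seeds <- split_seed(seed, 4)
  structure(
    list(experiment = experiment, n_subjects = n_subjects,
         n_sessions = n_sessions, seed = as.integer(seed),
         stage_seeds = list(simulate = stage_seeds[1], bold = stage_seeds[2],
                            fit = stage_seeds[3], report = stage_seeds[4]),
         agent_args = agent_args, task_args = task_args,
         glm_betas = glm_betas, out_dir = out_dir),
    class = "run_config"
  )
}

#' Write a session as a tab-separated event table with JSON sidecar
#'
#' One row per cue, response and outcome event with columns `onset`,
#' `duration`, `event`, `trial_type`, `offered`, `choice`, `rt_ms`,
#' `outcome`; the sidecar records the configuration and seed.
#'
#' @param trials Session data frame.
#' @param path Output `.tsv` path; the sidecar replaces the extension with
#'   `.json`.
#' @param config Optional configuration list for the sidecar.
#' @return `path`, invisibly.
#' @export
write_session_events <- function(trials, path, config = attr(trials, "config")) {
  n <- nrow(trials)
  trial_type <- if ("trial_type" %in% names(trials)) trials$trial_type else "choice"
  offered <- paste(trials$offered_1, trials$offered_2, sep = "+")
  side_1 <- if ("side_1" %in% names(trials)) trials$side_1 else "left"
  v_chosen <- if ("v_chosen" %in% names(trials)) trials$v_chosen else NA_real_
  v_unchosen <- if ("v_unchosen" %in% names(trials)) trials$v_unchosen else NA_real_
  outcome <- if ("outcome" %in% names(trials)) trials$outcome else trials$reward
  block <- function(event, onset, duration) {
    data.frame(onset = onset, duration = duration, event = event,
               trial = trials$trial, trial_type = trial_type,
               offered = offered, choice = trials$choice,
               side_1 = side_1, rt_ms = trials$rt_ms, outcome = outcome,
               v_chosen = v_chosen, v_unchosen = v_unchosen,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(block("cue", trials$t_cue, 0),
              block("response", trials$t_response, 0),
              block("outcome", trials$t_outcome, 0))
  ev <- ev[order(ev$onset), ]
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    side <- sub("\\.tsv$", ".json", path)
    jsonlite::write_json(config[setdiff(names(config), "reward_amounts")],
                         side, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a session event table back into one row per trial
#'
#' @param path A `.tsv` written by [write_session_events()].
#' @return Data frame with one row per trial (`offered_1`, `offered_2`,
#'   `choice`, `rt_ms`, `outcome`, `t_cue`, `t_response`, `t_outcome`).
#'   Numeric-looking stimulus labels are converted back to integers so
#'   reversal sessions round-trip.
#' @export
read_session_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(choice = "character"))
  cue <- ev[ev$event == "cue", ]
  cue <- cue[order(cue$trial), ]
  resp <- ev[ev$event == "response", ]
  resp <- resp[order(resp$trial), ]
  outc <- ev[ev$event == "outcome", ]
  outc <- outc[order(outc$trial), ]
  off <- strsplit(cue$offered, "+", fixed = TRUE)
  maybe_int <- function(x) {
    if (all(grepl("^[0-9]+$", x))) as.integer(x) else x
  }
  out <- data.frame(
    trial = cue$trial,
    trial_type = cue$trial_type,
    offered_1 = maybe_int(vapply(off, `[`, character(1), 1)),
    offered_2 = maybe_int(vapply(off, `[`, character(1), 2)),
    choice = maybe_int(cue$choice),
    side_1 = cue$side_1,
    rt_ms = cue$rt_ms,
    outcome = cue$outcome,
    v_chosen = cue$v_chosen,
    v_unchosen = cue$v_unchosen,
    t_cue = cue$onset,
    t_response = resp$onset,
    t_outcome = outc$onset,
    stringsAsFactors = FALSE
  )
  if (all(grepl("^[0-9]+$", out$choice))) {
    out$reward <- out$outcome  # reversal sessions store the binary reward
  }
  out
}

simulate_cohort <- function(config) {
  seeds <- matrix(split_seed(config$stage_seeds$simulate,
                             config$n_subjects * config$n_sessions),
                  config$n_subjects, config$n_sessions)
  sessions <- list()
  for (s in seq_len(config$n_subjects)) {
    for (k in seq_len(config$n_sessions)) {
      if (config$experiment == "lessismore") {
        agent <- do.call(subjective_agent, config$agent_args)
        cfg <- do.call(lessismore_config,
                       c(config$task_args, list(seed = seeds[s, k])))
        tr <- generate_lessismore_session(cfg, agent)
      } else {
        params <- do.call(rl_params,
                          if (length(config$agent_args) > 0) config$agent_args
                          else list(alpha = 0.3, temp = 0.2))
        cfg <- do.call(reversal_config,
                       c(config$task_args, list(seed = seeds[s, k])))
        tr <- generate_reversal_session(cfg, params)
      }
      tr$subject <- s
      tr$session <- k
      sessions[[length(sessions) + 1]] <- tr
    }
  }
  sessions
}

#' Simulate a cohort and write the artifact tree
#'
#' Generates `n_subjects x n_sessions` sessions of the configured task,
#' writes each as an events TSV with JSON sidecar, and writes a manifest
#' (config, seeds, file checksums) whose bytes are identical across
#' repeated runs of the same configuration.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly; artifacts land in
#'   `config$out_dir`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- simulate_cohort(config)
  files <- character(0)
  for (tr in sessions) {
    f <- file.path(config$out_dir,
                   sprintf("sub-%02d_ses-%02d_events.tsv",
                           tr$subject[1], tr$session[1]))
    write_session_events(tr, f)
    files <- c(files, f, sub("\\.tsv$", ".json", f))
  }
  manifest <- list(
    experiment = config$experiment, seed = config$seed,
    stage_seeds = config$stage_seeds,
    n_subjects = config$n_subjects, n_sessions = config$n_sessions,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Fit the RW/softmax model to every simulated reversal session
#'
#' Reads the event tables under `config$out_dir`, fits each session and
#' writes one CSV row per session (`subject`, `session`, `alpha_hat`,
#' `temp_hat`, `nll`, `n_trials`).
#'
#' @param config A [run_config()] with `experiment = "reversal"` whose
#'   [run_simulate()] artifacts exist.
#' @return The fits data frame, invisibly.
#' @export
run_fit_rl <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- list.files(config$out_dir, pattern = "_events\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no event tables under ", config$out_dir,
         "; run run_simulate() first", call. = FALSE)
  }
  seeds <- split_seed(config$stage_seeds$fit, length(files))
  rows <- list()
  for (i in seq_along(files)) {
    tr <- read_session_events(files[i])
    seqn <- as_choice_sequence(tr)
    fit <- fit_rl_session(seqn, seed = seeds[i])
    id <- regmatches(basename(files[i]),
                     regexec("sub-([0-9]+)_ses-([0-9]+)", basename(files[i])))[[1]]
    rows[[i]] <- data.frame(subject = as.integer(id[2]),
                            session = as.integer(id[3]),
                            alpha_hat = fit$alpha_hat,
                            temp_hat = fit$temp_hat, nll = fit$nll,
                            n_trials = fit$n_trials, seed = seeds[i])
  }
  fits <- do.call(rbind, rows)
  utils::write.csv(fits, file.path(config$out_dir, "rl_fits.csv"),
                   row.names = FALSE)
  invisible(fits)
}

#' Simulate BOLD, fit the parametric GLM and combine across sessions
#'
#' For every simulated session: generate a linear-forward-model ROI series
#' (negative value-difference effect by default), build the parametric
#' design, fit it, and extract the value-difference contrast; combine
#' sessions per subject by fixed effects and test the subject effects at
#' the group level. Results are written as CSV plus a JSON summary.
#'
#' @param config A [run_config()] whose [run_simulate()] artifacts exist.
#' @return List with `session_effects`, `subject_effects`, `group`,
#'   invisibly.
#' @export
run_glm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- list.files(config$out_dir, pattern = "_events\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no event tables under ", config$out_dir,
         "; run run_simulate() first", call. = FALSE)
  }
  betas <- utils::modifyList(list(decision = 1, diff = -0.8, sum = 0,
                                  outcome = 0.5), config$glm_betas)
  hrf <- gamma_hrf()
  seeds <- split_seed(config$stage_seeds$bold, length(files))
  rows <- list()
  for (i in seq_along(files)) {
    tr <- read_session_events(files[i])
    if (config$experiment == "lessismore") {
      vt <- stimulus_value_table(tr)
      vals <- build_trial_values(tr, vt)
      keep <- tr$choice %in% c("HV", "LV", "CV")
    } else {
      vals <- data.frame(trial = tr$trial, chosen = tr$v_chosen,
                         unchosen = tr$v_unchosen)
      keep <- rep(TRUE, nrow(tr))
    }
    n_vol <- ceiling((max(tr$t_outcome) + 16) / 2.28) + 1
    sim_tr <- tr
    sim_tr$v_chosen <- vals$chosen
    sim_tr$v_unchosen <- vals$unchosen
    bold <- generate_linear_roi(sim_tr[keep, ], betas, hrf, seed = seeds[i],
                                n_volumes = n_vol)
    design <- build_glm2(tr, vals, hrf, n_volumes = n_vol)
    fit <- fit_glm_session(bold, design)
    con <- contrast(fit, c(cue_cs_x_diff = 1), "chosen-unchosen value")
    id <- regmatches(basename(files[i]),
                     regexec("sub-([0-9]+)_ses-([0-9]+)", basename(files[i])))[[1]]
    rows[[i]] <- data.frame(subject = as.integer(id[2]),
                            session = as.integer(id[3]),
                            effect = con$effect, variance = con$variance,
                            t = con$t, p = con$p)
  }
  df <- do.call(rbind, rows)
  subj <- lapply(split(df, df$subject), function(d) {
    fe <- fixed_effects(d$effect, d$variance)
    data.frame(subject = d$subject[1], effect = fe$effect,
               variance = fe$variance)
  })
  subj <- do.call(rbind, subj)
  grp <- group_ttest(subj$effect)
  utils::write.csv(df, file.path(config$out_dir, "glm_session_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(subj, file.path(config$out_dir, "glm_subject_effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(grp, file.path(config$out_dir, "glm_group.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(session_effects = df, subject_effects = subj, group = grp))
}

#' Summary report of a simulated run
#'
#' Aggregates the behavioral checks of a run: trial-type allocation for
#' the single/choice task, or the chosen-stimulus re-offer rate (expected
#' 2/3) for the reversal task. Written as JSON.
#'
#' @param config A [run_config()] whose [run_simulate()] artifacts exist.
#' @return The report list, invisibly.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- list.files(config$out_dir, pattern = "_events\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no event tables under ", config$out_dir,
         "; run run_simulate() first", call. = FALSE)
  }
  sessions <- lapply(files, read_session_events)
  report <- list(experiment = config$experiment,
                 n_sessions = length(sessions))
  if (config$experiment == "reversal") {
    stacked <- do.call(rbind, lapply(seq_along(sessions), function(i) {
      s <- sessions[[i]]
      s$session <- i
      s
    }))
    report$reoffer_rate_pct <- reoffer_rate(stacked)
  } else {
    report$trial_counts <- as.list(table(sessions[[1]]$trial_type))
    report$mean_skip_rate <- mean(vapply(sessions, function(s) {
      mean(s$choice[s$trial_type == "single"] == "skip")
    }, numeric(1)))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
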