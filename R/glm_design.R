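# trials on which a rewarded stimulus was taken: CS+ labels for the
# single/choice task, any non-skip choice for label sets without CS+ names
# (e.g. integer stimuli of the reversal task)
cs_chosen_trials <- function(trials) {
  if (any(trials$choice %in% c("HV", "LV", "CV"))) {
    trials$choice %in% c("HV", "LV", "CV")
  } else {
    !(trials$choice %in% c("skip", "UNREW"))
  }
}

# side of the response: the screen side of whichever option was taken
response_side <- function(trials) {
  chose_first <- trials$choice == trials$offered_1
  other <- ifelse(trials$side_1 == "left", "right", "left")
  ifelse(chose_first, trials$side_1, other)
}

design_matrix <- function(X, unconvolved, dropped, modulators = NULL,
                          events = NULL) {
  structure(list(X = X, colnames = colnames(X), unconvolved = unconvolved,
                 dropped = dropped, modulators = modulators, events = events),
            class = "design_matrix")
}

# convolved event column on the volume grid
event_column <- function(onsets, amplitudes, hrf, tr, n_volumes) {
  if (length(onsets) == 0) return(numeric(n_volumes))
  convolve_events(onsets, amplitudes, hrf = hrf, tr = tr,
                  n_volumes = n_volumes)$values
}

# unconvolved spike column: 1 at the volume nearest each event
spike_column <- function(onsets, tr, n_volumes) {
  x <- numeric(n_volumes)
  idx <- pmin(pmax(round(onsets / tr) + 1, 1), n_volumes)
  x[idx] <- 1
  x
}

drop_empty_columns <- function(X, keep_warning = TRUE) {
  empty <- apply(X, 2, function(col) all(col == 0))
  if (any(empty) && keep_warning) {
    warning("dropping empty design column(s): ",
            paste(colnames(X)[empty], collapse = ", "), call. = FALSE)
  }
  list(X = X[, !empty, drop = FALSE], dropped = colnames(X)[empty])
}

#' Parametric (GLM-2) design matrix
#'
#' Ten columns: cue and outcome event regressors for trials on which a CS+
#' was taken and for trials on which none was (skip or CS- taken); two
#' parametric modulators on the CS+-chosen cue regressor - the normalized
#' sum of the offered values and the normalized chosen-unchosen difference
#' (built with [normalize_regressors()] and mean-centered by construction);
#' and four response regressors (left/right, HRF-convolved and unconvolved
#' spike versions). Conditions absent from the session yield empty columns,
#' which are dropped with a warning and recorded.
#'
#' @param trials Single/choice-task session data frame.
#' @param values Per-trial chosen/unchosen values from
#'   [build_trial_values()] (rows aligned with `trials`).
#' @param hrf An [gamma_hrf()] kernel.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes; default covers the session + 16 s.
#' @return A `design_matrix` whose `modulators` field carries the
#'   normalized regressors of the CS+-chosen trials.
#' @export
build_glm2 <- function(trials, values, hrf = gamma_hrf(), tr = 2.28,
                       n_volumes = NULL) {
  stopifnot(nrow(values) == nrow(trials))
  if (is.null(n_volumes)) {
    n_volumes <- ceiling((max(trials$t_outcome) + 16) / tr) + 1
  }
  cs <- cs_chosen_trials(trials)
  if (sum(cs) < 2) stop("need at least 2 CS+-chosen trials", call. = FALSE)
  if (anyNA(values$chosen[cs]) || anyNA(values$unchosen[cs])) {
    stop("missing chosen/unchosen value on a CS+-chosen trial", call. = FALSE)
  }
  mods <- normalize_regressors(values$chosen[cs], values$unchosen[cs])
  if (is.null(mods$sum_z)) {
    stop("value-sum modulator is constant across CS+-chosen trials",
         call. = FALSE)
  }
  side <- response_side(trials)
  X <- cbind(
    cue_cs = event_column(trials$t_cue[cs], 1, hrf, tr, n_volumes),
    cue_cs_x_sum = event_column(trials$t_cue[cs], mods$sum_z, hrf, tr, n_volumes),
    cue_cs_x_diff = event_column(trials$t_cue[cs], mods$diff_z, hrf, tr, n_volumes),
    out_cs = event_column(trials$t_outcome[cs], 1, hrf, tr, n_volumes),
    cue_nocs = event_column(trials$t_cue[!cs], 1, hrf, tr, n_volumes),
    out_nocs = event_column(trials$t_outcome[!cs], 1, hrf, tr, n_volumes),
    resp_left = event_column(trials$t_response[side == "left"], 1, hrf, tr, n_volumes),
    resp_right = event_column(trials$t_response[side == "right"], 1, hrf, tr, n_volumes),
    resp_left_spike = spike_column(trials$t_response[side == "left"], tr, n_volumes),
    resp_right_spike = spike_column(trials$t_response[side == "right"], tr, n_volumes)
  )
  pruned <- drop_empty_columns(X)
  design_matrix(pruned$X,
                unconvolved = c("resp_left_spike", "resp_right_spike"),
                dropped = pruned$dropped, modulators = mods,
                events = list(cs_trials = which(cs)))
}

# decision-type x choice condition label of each trial (provisional mapping
# for the synthetic task: 9 cells)
condition_label <- function(trials) {
  lab <- character(nrow(trials))
  single <- trials$trial_type == "single"
  lab[single & trials$choice == "skip"] <- "single_skip"
  lab[single & trials$choice != "skip"] <-
    paste0("single_", trials$choice[single & trials$choice != "skip"])
  csm <- trials$trial_type == "choice_cs_minus"
  lab[csm] <- ifelse(trials$choice[csm] == "UNREW", "csm_took_csminus",
                     "csm_took_csplus")
  csp <- trials$trial_type == "choice_cs_plus"
  if (any(csp)) {
    pair <- t(apply(cbind(trials$offered_1[csp], trials$offered_2[csp]), 1,
                    function(p) sort(p)))
    lab[csp] <- paste0("choice_", pair[, 1], "_", pair[, 2])
  }
  lab
}

#' Condition-based (GLM-1) design matrix
#'
#' Twenty-four columns: one cue-locked and one outcome-locked regressor per
#' decision-type x choice condition (nine conditions in the synthetic task)
#' plus a discarded-trials nuisance pair, and four response regressors
#' (left/right, convolved and unconvolved spikes). Conditions missing from
#' the session are dropped with a warning and recorded so contrast weights
#' can be renormalized.
#'
#' @param trials Single/choice-task session data frame.
#' @param hrf An [gamma_hrf()] kernel.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes; default covers the session + 16 s.
#' @param discard Logical vector flagging trials to route into the discard
#'   regressor (default: none).
#' @return A `design_matrix`.
#' @export
build_glm1 <- function(trials, hrf = gamma_hrf(), tr = 2.28,
                       n_volumes = NULL, discard = NULL) {
  if (is.null(n_volumes)) {
    n_volumes <- ceiling((max(trials$t_outcome) + 16) / tr) + 1
  }
  if (is.null(discard)) discard <- rep(FALSE, nrow(trials))
  lab <- condition_label(trials)
  if (any(lab == "")) {
    stop("unknown condition for trial(s) ",
         paste(which(lab == ""), collapse = ", "), call. = FALSE)
  }
  lab[discard] <- "discard"
  conditions <- c("single_HV", "single_LV", "single_CV", "single_skip",
                  "csm_took_csplus", "csm_took_csminus",
                  "choice_CV_HV", "choice_HV_LV", "choice_CV_LV", "discard")
  cols <- list()
  for (cond in conditions) {
    sel <- lab == cond
    cols[[paste0("cue_", cond)]] <-
      event_column(trials$t_cue[sel], 1, hrf, tr, n_volumes)
    cols[[paste0("out_", cond)]] <-
      event_column(trials$t_outcome[sel], 1, hrf, tr, n_volumes)
  }
  side <- response_side(trials)
  cols$resp_left <- event_column(trials$t_response[side == "left"], 1, hrf, tr, n_volumes)
  cols$resp_right <- event_column(trials$t_response[side == "right"], 1, hrf, tr, n_volumes)
  cols$resp_left_spike <- spike_column(trials$t_response[side == "left"], tr, n_volumes)
  cols$resp_right_spike <- spike_column(trials$t_response[side == "right"], tr, n_volumes)
  X <- do.call(cbind, cols)
  pruned <- drop_empty_columns(X)
  design_matrix(pruned$X,
                unconvolved = c("resp_left_spike", "resp_right_spike"),
                dropped = pruned$dropped,
                events = list(condition = lab))
}
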