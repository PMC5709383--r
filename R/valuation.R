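#' Choice counts per stimulus and presentation context
#'
#' Tallies, for every option, how often it was offered and how often it was
#' chosen in each disjoint context: against the blank side (single-option
#' trials), against a CS-, and against each other CS+. These counts are the
#' raw material of the frequency-based subjective-value estimate.
#'
#' @param trials A session (or several stacked sessions) from
#'   [generate_lessismore_session()].
#' @return A `data.frame` with columns `stimulus`, `context`, `n_offered`,
#'   `n_chosen`.
#' @export
choice_counts <- function(trials) {
  need <- c("offered_1", "offered_2", "choice")
  stopifnot(all(need %in% names(trials)))
  rows <- list()
  add <- function(stim, ctx, offered, chosen) {
    rows[[length(rows) + 1]] <<- data.frame(
      stimulus = stim, context = ctx,
      n_offered = offered, n_chosen = chosen,
      stringsAsFactors = FALSE)
  }
  opts <- sort(unique(c(trials$offered_1, trials$offered_2)))
  for (s in opts) {
    on_1 <- trials$offered_1 == s
    on_2 <- trials$offered_2 == s
    other <- ifelse(on_1, trials$offered_2, trials$offered_1)
    here <- on_1 | on_2
    for (ctx in sort(unique(other[here]))) {
      sel <- here & other == ctx
      ctx_label <- if (ctx == "blank") "vs_blank" else paste0("vs_", ctx)
      add(s, ctx_label, sum(sel), sum(trials$choice[sel] == s))
    }
  }
  do.call(rbind, rows)
}

#' Frequency-based subjective value of one stimulus
#'
#' For each context in which the stimulus was offered, the proportion of
#' offers on which it was chosen is weighted by the number of offers in that
#' context; the weighted proportions are summed and divided by the total
#' number of offers:
#'
#'   value = sum_c (prop_chosen_c * n_offered_c) / sum_c n_offered_c
#'
#' which algebraically equals total-times-chosen / total-times-offered. The
#' estimate lives on the \[0, 1\] proportion scale.
#'
#' @param counts Output of [choice_counts()].
#' @param stimulus Stimulus label.
#' @return Scalar value in \[0, 1\].
#' @export
empirical_value <- function(counts, stimulus) {
  rows <- counts[counts$stimulus == stimulus & counts$n_offered > 0, ]
  if (nrow(rows) == 0 || sum(rows$n_offered) == 0) {
    stop("stimulus '", stimulus, "' was never offered; value undefined",
         call. = FALSE)
  }
  prop <- rows$n_chosen / rows$n_offered
  sum(prop * rows$n_offered) / sum(rows$n_offered)
}

#' Per-animal table of empirical stimulus values
#'
#' @param trials A session (or stacked sessions) of the single/choice task.
#'   Skip choices are credited to the `"blank"` option, so blank acquires a
#'   value equal to the skip rate on single-option trials.
#' @return Named numeric vector of values in \[0, 1\], one per option ever
#'   offered, of class `stimulus_value_table`.
#' @export
stimulus_value_table <- function(trials) {
  tr <- trials
  tr$choice[tr$choice == "skip"] <- "blank"
  counts <- choice_counts(tr)
  opts <- sort(unique(counts$stimulus))
  vals <- vapply(opts, function(s) empirical_value(counts, s), numeric(1))
  names(vals) <- opts
  structure(vals, class = c("stimulus_value_table", class(vals)))
}

#' Per-trial chosen and unchosen values from a value table
#'
#' Looks up the value of the option taken and the option rejected, with no
#' reordering by magnitude (the chosen value may well be the lower one).
#' On single-option trials the rejected action is skipping, valued at
#' `skip_value`; on skipped trials the chosen value is `skip_value` and the
#' unchosen value is the declined option's.
#'
#' @param trials Single/choice-task session data frame.
#' @param values A [stimulus_value_table()] or named numeric vector.
#' @param skip_value Value of the skip action (default 0).
#' @return `data.frame` with columns `trial`, `chosen`, `unchosen`.
#' @export
build_trial_values <- function(trials, values, skip_value = 0) {
  lookup <- function(lab) {
    out <- numeric(length(lab))
    is_skip <- lab %in% c("skip", "blank")
    out[is_skip] <- skip_value
    if (any(!is_skip)) {
      unknown <- setdiff(unique(lab[!is_skip]), names(values))
      if (length(unknown) > 0) {
        stop("no value for stimulus label(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      out[!is_skip] <- unname(values[lab[!is_skip]])
    }
    out
  }
  took_first <- trials$choice == trials$offered_1
  rejected <- ifelse(took_first, trials$offered_2, trials$offered_1)
  data.frame(
    trial = trials$trial,
    chosen = lookup(trials$choice),
    unchosen = lookup(rejected)
  )
}

#' Independently normalized chosen / unchosen / difference regressors
#'
#' Z-scores the chosen values, the unchosen values, and the chosen-unchosen
#' difference each *separately*: the normalized difference is the z-score of
#' the raw difference, not the difference of the z-scores. Because the
#' chosen- and unchosen-value distributions differ, a trial's normalized
#' unchosen value can exceed its normalized chosen value even when the raw
#' chosen value is larger. The normalized sum is returned too, for the
#' "sum of offered values" parametric regressor.
#'
#' @param chosen,unchosen Per-trial raw value vectors (length >= 2 each).
#' @return A list of class `normalized_regressors` with `chosen_z`,
#'   `unchosen_z`, `diff_z`, `sum_z`; each has mean 0 and SD 1.
#' @export
normalize_regressors <- function(chosen, unchosen) {
  stopifnot(length(chosen) == length(unchosen), length(chosen) >= 2)
  zscore <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate regressor: ", what, " has zero variance",
           call. = FALSE)
    }
    (x - mean(x)) / s
  }
  sums <- chosen + unchosen
  structure(
    list(chosen_z = zscore(chosen, "chosen value"),
         unchosen_z = zscore(unchosen, "unchosen value"),
         diff_z = zscore(chosen - unchosen, "value difference"),
         # the sum can legitimately be constant (e.g. complementary
         # options); it is then unusable as a parametric regressor
         sum_z = if (stats::sd(sums) > 0) zscore(sums, "value sum") else NULL),
    class = "normalized_regressors"
  )
}
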