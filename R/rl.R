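#' Rescorla-Wagner / softmax parameters
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param temp Softmax stochasticity T > 0 (value units); lower values make
#'   choice more deterministic.
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(alpha, temp) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(temp) || temp <= 0) {
    stop("`temp` must be > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, temp = temp), class = "rl_params")
}

#' Delta-rule value update
#'
#' The chosen option's value moves toward the obtained reward by fraction
#' `alpha`; values of unchosen or unoffered options are carried forward
#' unchanged.
#'
#' @param values Numeric vector of current values, one per stimulus.
#' @param choice Index of the chosen stimulus.
#' @param reward Obtained reward.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value vector.
#' @export
rw_update <- function(values, choice, reward, alpha) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  values[choice] <- values[choice] + alpha * (reward - values[choice])
  values
}

#' Softmax choice probabilities over the offered set
#'
#' `P_s = exp(V_s / T) / sum_s' exp(V_s' / T)` with the sum running over
#' `offered`. Computed through the log-sum-exp identity so extreme
#' value/temperature ratios cannot underflow.
#'
#' @param values Numeric vector of values for all stimuli.
#' @param temp Stochasticity T > 0.
#' @param offered Indices of the available options (default: all).
#' @return Probability vector over `offered` (sums to 1), named by index.
#' @export
softmax_probs <- function(values, temp, offered = seq_along(values)) {
  if (temp <= 0) stop("`temp` must be > 0", call. = FALSE)
  if (length(offered) == 0) stop("`offered` must be nonempty", call. = FALSE)
  z <- values[offered] / temp
  z <- z - max(z)
  p <- exp(z)
  p <- p / sum(p)
  names(p) <- offered
  p
}

#' Extract a choice sequence from a reversal-session data frame
#'
#' @param trials Output of [generate_reversal_session()] (or a data frame
#'   with columns `offered_1`, `offered_2`, `choice`, `reward`).
#' @return A list of class `choice_sequence` with `offered` (N x 2 integer
#'   matrix), `choices`, `rewards` and `n_trials`.
#' @export
as_choice_sequence <- function(trials) {
  need <- c("offered_1", "offered_2", "choice", "reward")
  stopifnot(all(need %in% names(trials)))
  offered <- cbind(as.integer(trials$offered_1), as.integer(trials$offered_2))
  choices <- as.integer(trials$choice)
  ok <- choices == offered[, 1] | choices == offered[, 2]
  if (!all(ok)) {
    stop("choice outside the offered pair on trial(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  structure(list(offered = offered, choices = choices,
                 rewards = as.numeric(trials$reward),
                 n_trials = length(choices)),
            class = "choice_sequence")
}

#' Session negative log-likelihood of the RW/softmax model
#'
#' Forward pass over the session: on each trial the choice probability is
#' the softmax of the current value estimates (over the offered pair by
#' default, or over all stimuli when `all_options = TRUE`, matching the
#' convention in which the softmax denominator runs over every stimulus);
#' the chosen option's value is then updated toward the observed outcome.
#' Returns `L = -sum_t log P(c_t)`.
#'
#' @param params An [rl_params()] (or a numeric `c(alpha, temp)`).
#' @param sequence A `choice_sequence` from [as_choice_sequence()].
#' @param v0 Initial value for every stimulus (default 0.5).
#' @param n_stimuli Total number of stimuli (default: max index observed).
#' @param all_options Normalize the softmax over all stimuli instead of the
#'   offered pair.
#' @return Negative log-likelihood (non-negative scalar).
#' @export
session_nll <- function(params, sequence, v0 = 0.5, n_stimuli = NULL,
                        all_options = FALSE) {
  if (!inherits(params, "rl_params")) params <- rl_params(params[1], params[2])
  stopifnot(inherits(sequence, "choice_sequence"))
  if (is.null(n_stimuli)) n_stimuli <- max(sequence$offered)
  V <- rep(v0, n_stimuli)
  alpha <- params$alpha
  itemp <- 1 / params$temp
  nll <- 0
  for (t in seq_len(sequence$n_trials)) {
    set <- if (all_options) seq_len(n_stimuli) else sequence$offered[t, ]
    z <- V[set] * itemp
    # log P(c_t) via log-sum-exp
    logp <- V[sequence$choices[t]] * itemp - (max(z) + log(sum(exp(z - max(z)))))
    nll <- nll - logp
    c_t <- sequence$choices[t]
    V[c_t] <- V[c_t] + alpha * (sequence$rewards[t] - V[c_t])
  }
  nll
}

#' Fit RW/softmax parameters to one session by maximum likelihood
#'
#' Bounded quasi-Newton (`optim` method `"L-BFGS-B"`) minimization of the
#' session negative log-likelihood, restarted from a Latin-hypercube sample
#' of the (alpha, T) box so the reported optimum is never worse than any
#' evaluated start.
#'
#' @param sequence A `choice_sequence`.
#' @param v0 Initial stimulus value (default 0.5).
#' @param n_restarts Number of Latin-hypercube starting points (default 10).
#' @param alpha_bounds,temp_bounds Optimization box (defaults
#'   \[0.01, 0.99\] and \[0.01, 10\]).
#' @param all_options Passed to [session_nll()].
#' @param seed Optional seed for the restart sample.
#' @return An object of class `rl_fit`: `alpha_hat`, `temp_hat`, `nll`,
#'   `n_restarts`, `converged`, `n_trials`.
#' @export
fit_rl_session <- function(sequence, v0 = 0.5, n_restarts = 10,
                           alpha_bounds = c(0.01, 0.99),
                           temp_bounds = c(0.01, 10),
                           all_options = FALSE, seed = NULL) {
  stopifnot(inherits(sequence, "choice_sequence"))
  if (sequence$n_trials < 20) {
    warning("fewer than 20 trials; parameter estimates will be unstable",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_stimuli <- max(sequence$offered)
  obj <- function(par) {
    session_nll(rl_params(par[1], par[2]), sequence, v0 = v0,
                n_stimuli = n_stimuli, all_options = all_options)
  }
  starts <- lhs::randomLHS(n_restarts, 2)
  starts[, 1] <- alpha_bounds[1] + starts[, 1] * diff(alpha_bounds)
  # temperature sampled log-uniformly: its plausible range spans decades
  starts[, 2] <- exp(log(temp_bounds[1]) +
                       starts[, 2] * (log(temp_bounds[2]) - log(temp_bounds[1])))
  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = c(alpha_bounds[1], temp_bounds[1]),
                   upper = c(alpha_bounds[2], temp_bounds[2]),
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL
    )
    cand <- if (!is.null(res)) {
      any_converged <- any_converged || res$convergence == 0
      list(par = res$par, value = res$value)
    } else {
      list(par = starts[i, ], value = obj(starts[i, ]))
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (!any_converged) {
    stop("no optimizer start converged; best NLL ", signif(best$value, 6),
         " at alpha=", signif(best$par[1], 4), ", T=", signif(best$par[2], 4),
         call. = FALSE)
  }
  structure(
    list(alpha_hat = unname(best$par[1]), temp_hat = unname(best$par[2]),
         nll = best$value, n_restarts = n_restarts,
         converged = any_converged, n_trials = sequence$n_trials),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf(
    "RW/softmax fit: alpha = %.3f, T = %.3f, NLL = %.3f (%d trials, %d restarts)\n",
    x$alpha_hat, x$temp_hat, x$nll, x$n_trials, x$n_restarts))
  invisible(x)
}
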