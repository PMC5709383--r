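#' Two-pool attractor network parameters
#'
#' A reduced rate model of the decision circuit: two rectified, saturating
#' accumulators, one per choice option, with self-excitation `w_self`,
#' mutual inhibition `w_cross`, leak, a shared baseline drive and
#' value-proportional inputs. A decision is registered when either pool
#' crosses `threshold`. What happens afterwards is the `regime`:
#'
#' * `"decay"`: inputs and recurrence are withdrawn at the decision, so
#'   activity relaxes back to baseline. Total activity then mostly reflects
#'   *how long* the competition lasted, and harder decisions (small value
#'   difference) produce more integrated activity - the difficulty-positive,
#'   value-difference-negative signal.
#' * `"sustain"`: inputs are withdrawn but the winner's recurrent
#'   excitation keeps it in its high-activity attractor until trial end, so
#'   easy (fast) decisions accumulate *more* total activity - flipping the
#'   sign of the value-difference effect.
#'
#' Default magnitudes were chosen so that the mean decision time is about
#' 1 s for large value differences.
#'
#' @param w_self Recurrent self-excitation gain.
#' @param w_cross Cross-inhibition gain.
#' @param input_gain Gain on the option-value inputs.
#' @param leak Leak (decay) rate, 1/s.
#' @param baseline Shared constant drive.
#' @param noise_sd Diffusion SD of the accumulator noise (per sqrt(s)).
#' @param threshold Decision threshold on pool activity (> 0).
#' @param x_max Saturation ceiling of the rectified transfer (> threshold).
#' @param regime `"decay"` or `"sustain"` post-decision behavior.
#' @param dt Integration step in seconds.
#' @param max_decision_time Trials without a crossing before this time are
#'   flagged undecided.
#' @param trial_duration Simulated trial length in seconds.
#' @return An object of class `network_params`.
#' @export
network_params <- function(w_self = 3, w_cross = 4, input_gain = 0.5,
                           leak = 2.5, baseline = 0.4, noise_sd = 0.15,
                           threshold = 1, x_max = 1.2,
                           regime = c("decay", "sustain"),
                           dt = 0.002, max_decision_time = 3,
                           trial_duration = 8) {
  regime <- match.arg(regime)
  stopifnot(w_self >= 0, w_cross >= 0, input_gain >= 0, leak > 0,
            noise_sd >= 0, threshold > 0, x_max > threshold,
            dt > 0, max_decision_time > 0,
            trial_duration >= max_decision_time)
  structure(
    list(w_self = w_self, w_cross = w_cross, input_gain = input_gain,
         leak = leak, baseline = baseline, noise_sd = noise_sd,
         threshold = threshold, x_max = x_max, regime = regime,
         dt = dt, max_decision_time = max_decision_time,
         trial_duration = trial_duration),
    class = "network_params"
  )
}

# rectified-saturating transfer
rate_of <- function(x, x_max) pmin(pmax(x, 0), x_max)

#' Simulate a batch of attractor-network trials
#'
#' Euler-Maruyama integration of the two-pool model, vectorized across
#' trials. The aggregate (summed) pool activity is recorded on a coarser
#' `record_dt` grid for downstream HRF convolution. Ties (both pools
#' crossing on the same step) are broken toward the pool with the higher
#' activity, then toward pool 1; the tie-break is deterministic given the
#' seed.
#'
#' @param network A [network_params()].
#' @param v_a,v_b Input values of option A (pool 1) and option B (pool 2);
#'   vectors, one element per trial.
#' @param record_dt Recording resolution in seconds (default 0.1).
#' @param seed Optional seed.
#' @return A list: `choice` (1 = A, 2 = B, `NA` = undecided),
#'   `decision_time` (s, `NA` if undecided), `trace` (trials x timepoints
#'   aggregate activity), `trace_times`, `undecided` (logical).
#' @export
simulate_attractor_trials <- function(network, v_a, v_b, record_dt = 0.1,
                                      seed = NULL) {
  stopifnot(inherits(network, "network_params"),
            length(v_a) == length(v_b),
            all(is.finite(v_a)), all(is.finite(v_b)))
  if (!is.null(seed)) set.seed(seed)
  p <- network
  n <- length(v_a)
  n_steps <- round(p$trial_duration / p$dt)
  rec_every <- max(1L, round(record_dt / p$dt))
  n_rec <- floor(n_steps / rec_every)
  trace <- matrix(0, n, n_rec)
  x1 <- numeric(n)
  x2 <- numeric(n)
  choice <- rep(NA_integer_, n)
  decision_time <- rep(NA_real_, n)
  i1 <- p$input_gain * v_a + p$baseline
  i2 <- p$input_gain * v_b + p$baseline
  sn <- p$noise_sd * sqrt(p$dt)
  decided <- rep(FALSE, n)
  for (s in seq_len(n_steps)) {
    t_now <- s * p$dt
    r1 <- rate_of(x1, p$x_max)
    r2 <- rate_of(x2, p$x_max)
    und <- !decided
    if (any(und)) {
      dx1 <- -p$leak * x1[und] + p$w_self * r1[und] - p$w_cross * r2[und] + i1[und]
      dx2 <- -p$leak * x2[und] + p$w_self * r2[und] - p$w_cross * r1[und] + i2[und]
      x1[und] <- x1[und] + p$dt * dx1
      x2[und] <- x2[und] + p$dt * dx2
      if (sn > 0) {
        x1[und] <- x1[und] + sn * stats::rnorm(sum(und))
        x2[und] <- x2[und] + sn * stats::rnorm(sum(und))
      }
      if (t_now <= p$max_decision_time) {
        cross1 <- und & x1 >= p$threshold
        cross2 <- und & x2 >= p$threshold
        new1 <- cross1 & (!cross2 | x1 >= x2)
        new2 <- cross2 & !new1
        hit <- new1 | new2
        if (any(hit)) {
          choice[new1] <- 1L
          choice[new2] <- 2L
          decision_time[hit] <- t_now
          decided[hit] <- TRUE
        }
      } else {
        # past the deadline: whatever is still racing stays undecided and
        # enters the post-decision regime with no winner
        decided[und] <- TRUE
      }
    }
    if (any(decided)) {
      d <- decided
      if (p$regime == "decay") {
        x1[d] <- x1[d] * (1 - p$leak * p$dt)
        x2[d] <- x2[d] * (1 - p$leak * p$dt)
      } else {
        win1 <- d & !is.na(choice) & choice == 1L
        win2 <- d & !is.na(choice) & choice == 2L
        lose <- d & !(win1 | win2)
        r1d <- rate_of(x1, p$x_max)
        r2d <- rate_of(x2, p$x_max)
        x1[win1] <- x1[win1] + p$dt * (-p$leak * x1[win1] +
                                         p$w_self * r1d[win1] - p$w_cross * r2d[win1])
        x2[win1] <- x2[win1] + p$dt * (-p$leak * x2[win1] - p$w_cross * r1d[win1])
        x2[win2] <- x2[win2] + p$dt * (-p$leak * x2[win2] +
                                         p$w_self * r2d[win2] - p$w_cross * r1d[win2])
        x1[win2] <- x1[win2] + p$dt * (-p$leak * x1[win2] - p$w_cross * r2d[win2])
        x1[lose] <- x1[lose] * (1 - p$leak * p$dt)
        x2[lose] <- x2[lose] * (1 - p$leak * p$dt)
      }
      x1[d] <- pmax(x1[d], 0)
      x2[d] <- pmax(x2[d], 0)
    }
    if (s %% rec_every == 0) {
      trace[, s %/% rec_every] <- rate_of(x1, p$x_max) + rate_of(x2, p$x_max)
    }
  }
  list(choice = choice, decision_time = decision_time, trace = trace,
       trace_times = seq_len(n_rec) * rec_every * p$dt,
       undecided = is.na(choice))
}

#' Simulate a single attractor trial
#'
#' @inheritParams simulate_attractor_trials
#' @param v_left,v_right Input values of the left (pool 1) and right
#'   (pool 2) options.
#' @return A list with scalar `choice` (1 = left, 2 = right, `NA`),
#'   `decision_time`, the aggregate `trace` and `trace_times`.
#' @export
simulate_attractor_trial <- function(network, v_left, v_right,
                                     record_dt = 0.1, seed = NULL) {
  res <- simulate_attractor_trials(network, v_left, v_right, record_dt, seed)
  list(choice = res$choice[1], decision_time = res$decision_time[1],
       trace = res$trace[1, ], trace_times = res$trace_times)
}

#' ROI BOLD from the attractor network
#'
#' Simulates each trial's aggregate network activity (inputs are the
#' session's two option values per trial), places the traces at the trial
#' cue times on a fine time grid, convolves with the HRF and samples at the
#' TR grid. The network's own choices and decision times are attached.
#'
#' @param trials Session data frame with `t_cue` and per-trial input values
#'   `v_chosen`, `v_unchosen` (fed to the two pools; the model is symmetric
#'   in pool identity).
#' @param network A [network_params()].
#' @param hrf An [gamma_hrf()] kernel; its `dt` sets the recording grid.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes; default covers the session + 16 s.
#' @param measurement_noise Optional [bold_noise()] added after convolution.
#' @param seed Optional seed.
#' @return A [bold_series()] with attribute `"sim"` holding the per-trial
#'   simulation output.
#' @export
generate_attractor_roi <- function(trials, network, hrf = gamma_hrf(),
                                   tr = 2.28, n_volumes = NULL,
                                   measurement_noise = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_attractor_trials(network, trials$v_chosen,
                                   trials$v_unchosen, record_dt = hrf$dt)
  if (is.null(n_volumes)) {
    n_volumes <- ceiling((max(trials$t_cue) + network$trial_duration + 16) / tr) + 1
  }
  total <- (n_volumes - 1) * tr
  n_fine <- round(total / hrf$dt) + 1
  neural <- numeric(n_fine)
  nt <- ncol(sim$trace)
  for (i in seq_len(nrow(trials))) {
    j0 <- round(trials$t_cue[i] / hrf$dt) + 1
    j1 <- min(j0 + nt - 1, n_fine)
    if (j1 >= j0) {
      neural[j0:j1] <- neural[j0:j1] + sim$trace[i, seq_len(j1 - j0 + 1)]
    }
  }
  sig <- convolve_fine(neural, hrf)
  vol_idx <- round((0:(n_volumes - 1)) * tr / hrf$dt) + 1
  values <- sig[vol_idx] * hrf$dt  # scale by dt: integrated neural drive
  if (!is.null(measurement_noise)) {
    values <- values + draw_bold_noise(measurement_noise, n_volumes, tr)
  }
  out <- bold_series(values, tr)
  attr(out, "sim") <- sim
  out
}
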