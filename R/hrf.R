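#' Macaque gamma hemodynamic response kernel
#'
#' Discretized gamma-density HRF parameterized by its mean and width. The
#' macaque BOLD response is faster than the human one; the defaults (mean
#' 3 s, SD 1.5 s) give gamma shape `k = mean^2/sd^2 = 4` and scale
#' `theta = sd^2/mean = 0.75 s`. "Width" is interpreted as the standard
#' deviation by default; set `width_type = "fwhm"` to supply a full width at
#' half maximum instead (converted assuming the Gaussian relation
#' sd = fwhm / 2.355). The kernel is normalized to unit sum so convolution
#' preserves event amplitude.
#'
#' @param mean Kernel mean in seconds (> 0).
#' @param width Kernel width in seconds (> 0); SD or FWHM per `width_type`.
#' @param width_type `"sd"` (default) or `"fwhm"`.
#' @param dt Kernel resolution in seconds.
#' @param duration Kernel support length in seconds.
#' @return An object of class `hrf_kernel`: `kernel` (weights summing to 1),
#'   `times`, `dt`, `shape`, `scale`.
#' @export
gamma_hrf <- function(mean = 3, width = 1.5, width_type = c("sd", "fwhm"),
                      dt = 0.1, duration = 20) {
  width_type <- match.arg(width_type)
  if (mean <= 0 || width <= 0) stop("`mean` and `width` must be > 0", call. = FALSE)
  if (dt >= duration) stop("`dt` must be smaller than `duration`", call. = FALSE)
  sd <- if (width_type == "fwhm") width / (2 * sqrt(2 * log(2))) else width
  shape <- mean^2 / sd^2
  scale <- sd^2 / mean
  times <- seq(0, duration, by = dt)
  k <- stats::dgamma(times, shape = shape, scale = scale)
  k <- k / sum(k)
  structure(
    list(kernel = k, times = times, dt = dt, mean = mean, sd = sd,
         shape = shape, scale = scale),
    class = "hrf_kernel"
  )
}

#' BOLD time series container
#'
#' @param values Signal values, one per volume.
#' @param tr Repetition time in seconds (> 0); volume `i` samples time
#'   `(i - 1) * tr`.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(values, tr = 2.28) {
  stopifnot(is.numeric(values), tr > 0)
  structure(list(values = as.numeric(values), tr = tr,
                 n_volumes = length(values)),
            class = "bold_series")
}

#' Convolve an event train with the HRF and sample on the volume grid
#'
#' Events are placed as deltas (or boxcars when `durations > 0`) on the
#' kernel-resolution grid, convolved with the HRF, and the result is read
#' out at volume times `0, tr, 2 tr, ...`. The operation is exactly linear
#' in the amplitudes.
#'
#' @param onsets Event onsets in seconds.
#' @param amplitudes Event amplitudes (recycled; default 1).
#' @param hrf An [gamma_hrf()] kernel.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes of the output series.
#' @param durations Event durations in seconds (0 = delta; recycled).
#' @return A [bold_series()].
#' @export
convolve_events <- function(onsets, amplitudes = 1, hrf, tr = 2.28,
                            n_volumes, durations = 0) {
  stopifnot(inherits(hrf, "hrf_kernel"), n_volumes >= 1)
  n <- length(onsets)
  amplitudes <- rep_len(amplitudes, n)
  durations <- rep_len(durations, n)
  total <- (n_volumes - 1) * tr
  if (n > 0 && any(onsets < 0 | onsets > total)) {
    stop("event onset outside the recording (0 to ", total, " s)",
         call. = FALSE)
  }
  fine <- fine_event_train(onsets, amplitudes, durations, hrf$dt, total)
  sig <- convolve_fine(fine, hrf)
  vol_idx <- round((0:(n_volumes - 1)) * tr / hrf$dt) + 1
  bold_series(sig[vol_idx], tr)
}

# amplitude train on the dt grid covering [0, total]; boxcar events spread
# their amplitude over ceiling(duration/dt) bins
fine_event_train <- function(onsets, amplitudes, durations, dt, total) {
  n_fine <- round(total / dt) + 1
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    j0 <- round(onsets[i] / dt) + 1
    if (durations[i] <= 0) {
      x[j0] <- x[j0] + amplitudes[i]
    } else {
      j1 <- min(j0 + ceiling(durations[i] / dt) - 1, n_fine)
      x[j0:j1] <- x[j0:j1] + amplitudes[i]
    }
  }
  x
}

# causal convolution of a fine-grid train with the kernel, truncated to the
# train's length
convolve_fine <- function(x, hrf) {
  full <- stats::convolve(x, rev(hrf$kernel), type = "open")
  full[seq_along(x)]
}

#' AR(1) + white noise + slow drift model for synthetic BOLD
#'
#' Default magnitudes are scaled to the unit-sum HRF kernel used by
#' [convolve_events()], under which a unit-amplitude event produces a
#' sampled response with peak about 0.07: the defaults give an ROI-mean
#' time series whose event responses are clearly visible but individual
#' trials are noisy, as in averaged ROI data.
#'
#' @param ar_coef AR(1) coefficient of the colored component (default 0.3).
#' @param ar_sd Stationary SD of the AR(1) component.
#' @param white_sd SD of the additional white component.
#' @param drift_sd Amplitude SD of a slow cosine drift (0 disables it).
#' @param drift_period Drift period in seconds; longer than the high-pass
#'   cutoff so the filtering step can remove it.
#' @return An object of class `bold_noise`.
#' @export
bold_noise <- function(ar_coef = 0.3, ar_sd = 0.05, white_sd = 0.025,
                       drift_sd = 0, drift_period = 256) {
  stopifnot(abs(ar_coef) < 1, ar_sd >= 0, white_sd >= 0, drift_sd >= 0,
            drift_period > 0)
  structure(list(ar_coef = ar_coef, ar_sd = ar_sd, white_sd = white_sd,
                 drift_sd = drift_sd, drift_period = drift_period),
            class = "bold_noise")
}

# one realization of the noise model on an n-volume TR grid
draw_bold_noise <- function(noise, n_volumes, tr) {
  eps <- numeric(n_volumes)
  if (noise$ar_sd > 0) {
    innov_sd <- noise$ar_sd * sqrt(1 - noise$ar_coef^2)  # stationary sd = ar_sd
    eps <- eps + as.numeric(stats::arima.sim(
      model = list(ar = noise$ar_coef), n = n_volumes, sd = innov_sd))
  }
  if (noise$white_sd > 0) eps <- eps + stats::rnorm(n_volumes, 0, noise$white_sd)
  if (noise$drift_sd > 0) {
    t <- (0:(n_volumes - 1)) * tr
    amp <- stats::rnorm(1, 0, noise$drift_sd)
    phase <- stats::runif(1, 0, 2 * pi)
    eps <- eps + amp * cos(2 * pi * t / noise$drift_period + phase)
  }
  eps
}
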