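#' Subjective-value agent for the single/choice ("less-is-more") task
#'
#' An agent that holds fixed subjective values for the high-value (HV),
#' low-value (LV) and unrewarded (UNREW, the CS-) options and derives the
#' value of the compound (CV = HV juice + LV juice) option from a bias
#' parameter `cv_bias` that interpolates between the *sum* and the *mean* of
#' the component values:
#'
#'   v_CV = cv_bias * mean(v_hv, v_lv) + (1 - cv_bias) * (v_hv + v_lv)
#'
#' `cv_bias = 1` yields averaging, i.e. the "less-is-more" ordering
#' v_HV > v_CV > v_LV seen in intact animals; `cv_bias = 0` yields objective
#' summation (CV most valuable), the pattern expected if the compound were
#' valued by total reward amount.
#'
#' @param v_hv,v_lv,v_unrew Subjective values of the HV, LV and unrewarded
#'   options (arbitrary value units).
#' @param cv_bias Mean-vs-sum interpolation weight in \[0, 1\].
#' @param temperature Softmax stochasticity (> 0), in the same units as the
#'   values; lower is more deterministic.
#' @param skip_value Value assigned to skipping a single-option trial.
#' @return An object of class `subjective_agent` with a `values` lookup
#'   containing HV, LV, CV, UNREW and blank (= `skip_value`).
#' @export
subjective_agent <- function(v_hv = 1, v_lv = 0.4, v_unrew = 0,
                             cv_bias = 1, temperature = 0.15,
                             skip_value = 0) {
  stopifnot(is.finite(v_hv), is.finite(v_lv), is.finite(v_unrew))
  if (cv_bias < 0 || cv_bias > 1) {
    stop("`cv_bias` must lie in [0, 1]", call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  v_cv <- cv_bias * mean(c(v_hv, v_lv)) + (1 - cv_bias) * (v_hv + v_lv)
  structure(
    list(
      values = c(HV = v_hv, LV = v_lv, CV = v_cv, UNREW = v_unrew,
                 blank = skip_value),
      cv_bias = cv_bias,
      temperature = temperature
    ),
    class = "subjective_agent"
  )
}

#' Linear reaction-time model
#'
#' Generates reaction times as a linear function of the summed and
#' differenced values of the chosen and unchosen options,
#' `rt = intercept + b_sum * (v_c + v_u) + b_diff * (v_c - v_u) + noise`,
#' truncated below at `floor_ms`. Negative `b_sum` and `b_diff` reproduce
#' the empirical pattern: animals respond faster when the options are
#' valuable overall and when the decision is easy (large value difference).
#'
#' @param intercept_ms Baseline RT in milliseconds.
#' @param b_sum,b_diff Slopes in ms per value unit (typically negative).
#' @param noise_sd Gaussian noise SD in ms.
#' @param floor_ms Truncation floor in ms; generated RTs never fall below it.
#' @return An object of class `rt_model`.
#' @export
rt_model <- function(intercept_ms = 1000, b_sum = -100, b_diff = -50,
                     noise_sd = 50, floor_ms = 250) {
  stopifnot(is.finite(intercept_ms), is.finite(b_sum), is.finite(b_diff),
            noise_sd >= 0, floor_ms >= 0)
  structure(
    list(intercept_ms = intercept_ms, b_sum = b_sum, b_diff = b_diff,
         noise_sd = noise_sd, floor_ms = floor_ms),
    class = "rt_model"
  )
}

#' Simulate reaction times from an `rt_model`
#'
#' @param model An [rt_model()].
#' @param v_chosen,v_unchosen Values of the chosen and unchosen options
#'   (vectors are recycled to a common length).
#' @return Numeric vector of RTs in milliseconds, truncated at the model
#'   floor.
#' @export
simulate_rt <- function(model, v_chosen, v_unchosen) {
  stopifnot(inherits(model, "rt_model"),
            all(is.finite(v_chosen)), all(is.finite(v_unchosen)))
  n <- max(length(v_chosen), length(v_unchosen))
  v_chosen <- rep_len(v_chosen, n)
  v_unchosen <- rep_len(v_unchosen, n)
  rt <- model$intercept_ms +
    model$b_sum * (v_chosen + v_unchosen) +
    model$b_diff * (v_chosen - v_unchosen)
  if (model$noise_sd > 0) rt <- rt + stats::rnorm(n, 0, model$noise_sd)
  pmax(rt, model$floor_ms)
}
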