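#' Spherical ROI mask
#'
#' @param center Center voxel (1-based integer coordinates, length 3).
#' @param radius Sphere radius in voxels (default 2); membership is
#'   Euclidean distance <= radius on the integer lattice, so a radius-2
#'   sphere contains 33 voxels.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(center, radius = 2) {
  stopifnot(length(center) == 3, radius >= 0)
  structure(list(center = center, radius = radius), class = "roi_mask")
}

# integer lattice offsets within a Euclidean ball
sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
}

#' Mean ROI time course from a voxel grid
#'
#' @param grid A `bold_grid` from [generate_linear_grid()].
#' @param mask An [roi_mask()]; must lie fully inside the grid.
#' @return A [bold_series()] of the per-volume mean over in-sphere voxels.
#' @export
extract_roi <- function(grid, mask) {
  stopifnot(inherits(grid, "bold_grid"), inherits(mask, "roi_mask"))
  dims <- dim(grid$data)[1:3]
  off <- sphere_offsets(mask$radius)
  vox <- cbind(mask$center[1] + off$x, mask$center[2] + off$y,
               mask$center[3] + off$z)
  if (nrow(vox) == 0) stop("empty mask", call. = FALSE)
  if (any(vox < 1) || any(vox[, 1] > dims[1]) || any(vox[, 2] > dims[2]) ||
      any(vox[, 3] > dims[3])) {
    stop("mask extends beyond the grid", call. = FALSE)
  }
  nt <- dim(grid$data)[4]
  acc <- numeric(nt)
  for (i in seq_len(nrow(vox))) {
    acc <- acc + grid$data[vox[i, 1], vox[i, 2], vox[i, 3], ]
  }
  bold_series(acc / nrow(vox), grid$tr)
}

#' Decision-locked epoching with linear upsampling
#'
#' Interpolates the volume-grid series onto a fine event-relative grid
#' (default 0.25 s steps over -2 to +14 s around each event). Events whose
#' window leaves the recording are dropped and reported. Optionally
#' subtracts each trial's mean pre-event signal as baseline.
#'
#' @param series A [bold_series()].
#' @param events Event (decision-onset) times in seconds.
#' @param window Epoch window relative to the event, seconds.
#' @param step Upsampled resolution in seconds.
#' @param baseline `"none"` (default) or `"pre_event"` (subtract the mean
#'   of the pre-event part of each epoch).
#' @return An object of class `epoched_timecourse`: `mat` (trials x
#'   timepoints), `time`, `kept` (indices of retained events), `dropped`.
#' @export
epoch_upsample <- function(series, events, window = c(-2, 14), step = 0.25,
                           baseline = c("none", "pre_event")) {
  stopifnot(inherits(series, "bold_series"), window[1] < window[2], step > 0)
  baseline <- match.arg(baseline)
  vol_t <- (seq_len(series$n_volumes) - 1) * series$tr
  rel <- seq(window[1], window[2], by = step)
  ok <- events + window[1] >= vol_t[1] & events + window[2] <= vol_t[length(vol_t)]
  if (!any(ok)) stop("no event fits inside the recording", call. = FALSE)
  kept <- which(ok)
  mat <- t(vapply(events[kept], function(e) {
    stats::approx(vol_t, series$values, xout = e + rel)$y
  }, numeric(length(rel))))
  if (baseline == "pre_event" && any(rel < 0)) {
    mat <- mat - rowMeans(mat[, rel < 0, drop = FALSE])
  }
  structure(list(mat = mat, time = rel, kept = kept,
                 dropped = which(!ok), baseline = baseline),
            class = "epoched_timecourse")
}

#' Across-trial regression at every epoch timepoint
#'
#' At each event-relative timepoint, regresses the signal across trials on
#' the supplied per-trial regressors (plus an intercept) and stores the
#' coefficient ("effect size") and its standard error.
#'
#' @param epochs An `epoched_timecourse`.
#' @param regressors Data frame of per-trial regressors, rows aligned with
#'   the *retained* trials (`epochs$kept`).
#' @return An object of class `timepoint_betas`: `time`, `betas` and `se`
#'   (timepoints x regressors matrices, intercept included), `names`.
#' @export
timepoint_regression <- function(epochs, regressors) {
  stopifnot(inherits(epochs, "epoched_timecourse"))
  regressors <- as.data.frame(regressors)
  if (nrow(regressors) != nrow(epochs$mat)) {
    stop("need one regressor row per retained trial", call. = FALSE)
  }
  X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(X) <= ncol(X)) {
    stop("fewer trials than regressors", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear trial regressors", call. = FALSE)
  betas <- qr.coef(qx, epochs$mat)           # k x T
  fitted <- X %*% betas
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums((epochs$mat - fitted)^2) / dof
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(X))))
  se <- t(sqrt(outer(xtx_inv_diag, sigma2)))  # T x k
  dimnames(se) <- list(NULL, colnames(X))
  structure(list(time = epochs$time, betas = t(betas), se = se,
                 names = colnames(X), dof = dof),
            class = "timepoint_betas")
}

#' Leave-one-out peak selection and test
#'
#' For each held-out session the peak timepoint (or voxel) is chosen from
#' the *mean* effect curve of all other sessions, the held-out session's
#' value at that index is collected, and the collected values are tested
#' against zero with a two-tailed one-sample t-test. Selecting on
#' independent data keeps the test unbiased; the same function with
#' `fold = FALSE` performs the biased same-data selection for comparison.
#'
#' @param mat Sessions x points matrix of effect estimates (beta time
#'   courses or voxel-wise maps).
#' @param mode `"absmax"` (default) selects the extremum of the absolute
#'   mean curve - appropriate when the effect may be negative - recording
#'   its sign; `"max"` selects the literal maximum.
#' @param fold `TRUE` for leave-one-out selection, `FALSE` for (biased)
#'   selection on the mean of all sessions.
#' @return A list of class `loo_peak`: `values` (one per session),
#'   `indices` (selected point per fold), `t`, `p`, `dof`, `mode`.
#' @export
loo_peak_stat <- function(mat, mode = c("absmax", "max"), fold = TRUE) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3) stop("need >= 3 sessions for leave-one-out selection", call. = FALSE)
  pick <- function(m) if (mode == "absmax") which.max(abs(m)) else which.max(m)
  indices <- integer(n)
  values <- numeric(n)
  for (i in seq_len(n)) {
    m <- if (fold) colMeans(mat[-i, , drop = FALSE]) else colMeans(mat)
    indices[i] <- pick(m)
    values[i] <- mat[i, indices[i]]
  }
  tt <- tryCatch(stats::t.test(values), error = function(e) NULL)
  structure(list(values = values, indices = indices,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 dof = length(values) - 1, mode = mode, fold = fold),
            class = "loo_peak")
}

#' Group-level leave-one-out peak test across subjects
#'
#' The full unbiased read-out: within every subject, each session's peak
#' timepoint (or voxel) is selected from the mean effect curve of that
#' subject's *other* sessions ([loo_peak_stat()]), the held-out values are
#' averaged into one number per subject, and the subject aggregates are
#' tested against zero with a two-tailed one-sample t-test. Because each
#' subject's aggregate has zero expectation under the null and subjects
#' are independent, this test is calibrated. With `biased = TRUE` the
#' classic circular alternative is computed instead: one common peak is
#' selected from the grand mean over every session of every subject
#' (including the data being tested), which inflates the false-positive
#' rate badly.
#'
#' Note that a one-sample t-test directly across held-out *sessions* of a
#' single subject is not calibrated even with leave-one-out selection: the
#' session values share their selection folds and are therefore positively
#' correlated. The session-level [loo_peak_stat()] is the per-subject
#' building block; inference belongs at this level.
#'
#' @param subject_mats List with one sessions x points matrix per subject
#'   (>= 2 subjects, >= 3 sessions each).
#' @param mode Peak definition, as in [loo_peak_stat()].
#' @param biased Use the circular common-peak selection instead of
#'   within-subject leave-one-out.
#' @return A list of class `loo_group`: `subject_values`, `t`, `p`, `dof`,
#'   `folds` (per-subject `loo_peak` results when `biased = FALSE`).
#' @export
loo_group_stat <- function(subject_mats, mode = c("absmax", "max"),
                           biased = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.list(subject_mats), length(subject_mats) >= 2)
  folds <- NULL
  if (biased) {
    grand <- colMeans(do.call(rbind, subject_mats))
    j <- if (mode == "absmax") which.max(abs(grand)) else which.max(grand)
    values <- vapply(subject_mats, function(m) mean(m[, j]), numeric(1))
  } else {
    folds <- lapply(subject_mats, loo_peak_stat, mode = mode)
    values <- vapply(folds, function(f) mean(f$values), numeric(1))
  }
  tt <- stats::t.test(values)
  structure(list(subject_values = values, t = unname(tt$statistic),
                 p = tt$p.value, dof = unname(tt$parameter),
                 folds = folds, biased = biased),
            class = "loo_group")
}

#' Per-trial peak analysis over a fixed post-stimulus window
#'
#' Takes each trial's maximum signal within `window` (default 1.5-6.5 s
#' after the decision cue), averages the peaks per condition cell, and -
#' when `conditions` provides `subject`, `chosen` and `unchosen` factors -
#' runs a chosen x unchosen repeated-measures ANOVA on the subject cell
#' means.
#'
#' @param epochs An `epoched_timecourse`.
#' @param conditions Data frame aligned with retained trials; columns
#'   `chosen` and `unchosen` (factors/labels) and optionally `subject`.
#' @param window Peak-search window in seconds relative to the event.
#' @return A list: `peaks` (per trial), `cell_means`, and `anova` (an
#'   [rm_anova()] table when a `subject` column is present, else `NULL`).
#' @export
trial_peak_analysis <- function(epochs, conditions, window = c(1.5, 6.5)) {
  stopifnot(inherits(epochs, "epoched_timecourse"))
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) != nrow(epochs$mat)) {
    stop("need one condition row per retained trial", call. = FALSE)
  }
  in_win <- epochs$time >= window[1] & epochs$time <= window[2]
  if (!any(in_win)) stop("peak window outside the epoch window", call. = FALSE)
  peaks <- apply(epochs$mat[, in_win, drop = FALSE], 1, max)
  cell <- interaction(conditions$chosen, conditions$unchosen, sep = " vs ",
                      drop = TRUE)
  cell_means <- tapply(peaks, cell, mean)
  anova_res <- NULL
  if ("subject" %in% names(conditions)) {
    agg <- stats::aggregate(
      list(peak = peaks),
      by = list(subject = conditions$subject, chosen = conditions$chosen,
                unchosen = conditions$unchosen),
      FUN = mean)
    anova_res <- rm_anova(agg, dv = "peak",
                          within = c("chosen", "unchosen"),
                          subject = "subject")
  }
  list(peaks = peaks, cell_means = cell_means, anova = anova_res)
}
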