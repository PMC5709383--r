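#' Linear forward model of ROI BOLD activity
#'
#' Generates a synthetic ROI time series in which every decision event
#' evokes an amplitude
#' `beta_decision + beta_diff * diff_z + beta_sum * sum_z`, where `diff_z`
#' and `sum_z` are the session's independently normalized chosen-unchosen
#' difference and chosen+unchosen sum (see [normalize_regressors()]), and
#' every outcome event evokes `beta_outcome` (plus, optionally,
#' `beta_outcome_chosen * chosen_z`, mimicking reactivation of the chosen
#' option's value at outcome time). Event amplitudes are convolved with the
#' HRF and sampled at the TR grid; AR(1) + white + drift noise is added.
#' A negative `beta_diff` reproduces the macaque-like pattern in which ROI
#' activity *decreases* as decisions get easier.
#'
#' @param trials Session data frame with `t_cue`, `t_outcome`, `v_chosen`,
#'   `v_unchosen`.
#' @param betas Named list: `decision`, `diff`, `sum`, `outcome`, and
#'   optionally `outcome_chosen` (defaults 1, -1, 0, 0.5, 0).
#' @param hrf An [gamma_hrf()] kernel.
#' @param noise A [bold_noise()] model, or `NULL` for a noiseless series.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes; default covers the session plus 16 s.
#' @param seed Optional seed (fixed seed gives a bit-identical series).
#' @return A [bold_series()] with attributes `"amplitudes"` (per decision
#'   event) and `"modulators"` (the normalized regressors used).
#' @export
generate_linear_roi <- function(trials, betas = list(), hrf = gamma_hrf(),
                                noise = bold_noise(), tr = 2.28,
                                n_volumes = NULL, seed = NULL) {
  b <- utils::modifyList(
    list(decision = 1, diff = -1, sum = 0, outcome = 0.5, outcome_chosen = 0),
    betas)
  if (!is.null(seed)) set.seed(seed)
  mods <- normalize_regressors(trials$v_chosen, trials$v_unchosen)
  if (is.null(n_volumes)) {
    n_volumes <- ceiling((max(trials$t_outcome) + 16) / tr) + 1
  }
  amp_dec <- b$decision + b$diff * mods$diff_z + b$sum * mods$sum_z
  amp_out <- rep(b$outcome, nrow(trials)) + b$outcome_chosen * mods$chosen_z
  clean <- convolve_events(c(trials$t_cue, trials$t_outcome),
                           c(amp_dec, amp_out),
                           hrf = hrf, tr = tr, n_volumes = n_volumes)
  values <- clean$values
  if (!is.null(noise)) values <- values + draw_bold_noise(noise, n_volumes, tr)
  out <- bold_series(values, tr)
  attr(out, "amplitudes") <- amp_dec
  attr(out, "modulators") <- mods
  out
}

#' Linear forward model on a voxel grid
#'
#' Places the decision-value effect of [generate_linear_roi()] in a
#' spherical blob with a Gaussian spatial profile (unit amplitude at
#' `center`, SD `blob_sd` voxels, truncated at `blob_radius`); every voxel
#' receives its own independent noise realization. Used by the spatial
#' leave-one-out analyses.
#'
#' @param trials,betas,hrf,noise,tr,n_volumes,seed As in
#'   [generate_linear_roi()].
#' @param dim Grid dimensions in voxels, length 3.
#' @param center Blob center voxel (1-based), length 3.
#' @param blob_radius Truncation radius of the effect blob, in voxels.
#' @param blob_sd Gaussian profile SD in voxels.
#' @return An object of class `bold_grid`: `data` (4-D array x,y,z,t),
#'   `tr`, `center`, `profile` (3-D array of effect weights).
#' @export
generate_linear_grid <- function(trials, betas = list(), hrf = gamma_hrf(),
                                 noise = bold_noise(), tr = 2.28,
                                 dim = c(9, 9, 9), center = c(5, 5, 5),
                                 blob_radius = 3, blob_sd = 1.5,
                                 n_volumes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clean <- generate_linear_roi(trials, betas, hrf, noise = NULL, tr = tr,
                               n_volumes = n_volumes)
  nt <- clean$n_volumes
  profile <- array(0, dim)
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2])) for (k in seq_len(dim[3])) {
    d2 <- sum((c(i, j, k) - center)^2)
    if (d2 <= blob_radius^2) profile[i, j, k] <- exp(-d2 / (2 * blob_sd^2))
  }
  data <- array(0, c(dim, nt))
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2])) for (k in seq_len(dim[3])) {
    vox <- profile[i, j, k] * clean$values
    if (!is.null(noise)) vox <- vox + draw_bold_noise(noise, nt, tr)
    data[i, j, k, ] <- vox
  }
  structure(list(data = data, tr = tr, center = center, profile = profile),
            class = "bold_grid")
}

#' Write a BOLD series as a two-column TSV (time, signal)
#'
#' @param series A [bold_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bold_tsv <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  df <- data.frame(time = (seq_len(series$n_volumes) - 1) * series$tr,
                   signal = series$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a voxel-grid BOLD dataset as NIfTI
#'
#' Requires the `RNifti` package.
#'
#' @param grid A `bold_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "bold_grid"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- c(1, 1, 1, grid$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export an HRF kernel as CSV
#'
#' @param hrf An [gamma_hrf()] kernel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hrf_csv <- function(hrf, path) {
  stopifnot(inherits(hrf, "hrf_kernel"))
  utils::write.csv(data.frame(time = hrf$times, weight = hrf$kernel),
                   path, row.names = FALSE)
  invisible(path)
}
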