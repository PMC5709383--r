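#' Low-frequency nuisance basis for high-pass filtering
#'
#' Sine/cosine pairs at half-harmonic spacing (frequencies `j / (2 n tr)`
#' up to `1 / cutoff`) plus a constant. Projecting data and design onto
#' the orthogonal complement of this span removes fluctuations slower than
#' the cutoff essentially completely - including drifts whose period is
#' not a harmonic of the record length - while leaving task-band signal
#' (periods well below the cutoff) almost untouched.
#'
#' @param n_volumes Number of volumes.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff in seconds (default 100).
#' @return `n_volumes x K` basis matrix.
#' @export
highpass_basis <- function(n_volumes, tr, cutoff = 100) {
  total <- n_volumes * tr
  t_s <- (seq_len(n_volumes) - 1) * tr
  j_max <- floor(2 * total / cutoff)
  cols <- list(rep(1, n_volumes))
  for (j in seq_len(j_max)) {
    f <- j / (2 * total)
    cols[[length(cols) + 1]] <- cos(2 * pi * f * t_s)
    cols[[length(cols) + 1]] <- sin(2 * pi * f * t_s)
  }
  do.call(cbind, cols)
}

# residualize columns of M against the span of B (rank-deficiency safe)
project_out <- function(M, B) {
  stats::lm.fit(B, M)$residuals
}

#' Apply the high-pass filter to a numeric vector
#'
#' @param x Signal values.
#' @param tr Repetition time in seconds.
#' @param cutoff Cutoff in seconds.
#' @return Filtered vector (slow components and mean removed).
#' @export
highpass_filter <- function(x, tr, cutoff = 100) {
  B <- highpass_basis(length(x), tr, cutoff)
  as.numeric(project_out(matrix(x, ncol = 1), B))
}

#' Fit one session's GLM by ordinary least squares
#'
#' Both the data and every design column are passed through the identical
#' high-pass filter (projection onto the complement of [highpass_basis()],
#' 100 s cutoff by default), then betas are estimated by OLS. Residual degrees of freedom subtract
#' both the design rank and the filter basis dimension.
#'
#' @param bold A [bold_series()] (or numeric vector with `tr` attribute
#'   taken from `design` call - prefer the class).
#' @param design A `design_matrix` from [build_glm1()]/[build_glm2()].
#' @param highpass Cutoff in seconds; `NULL` disables filtering (an
#'   intercept column is then appended instead).
#' @return An object of class `session_fit`: `betas`, `se`, `xtx_inv`,
#'   `sigma2`, `dof`, `colnames`.
#' @export
fit_glm_session <- function(bold, design, highpass = 100) {
  stopifnot(inherits(bold, "bold_series"), inherits(design, "design_matrix"))
  y <- bold$values
  X <- design$X
  if (nrow(X) != length(y)) {
    stop("design has ", nrow(X), " rows but the series has ", length(y),
         " volumes", call. = FALSE)
  }
  if (!is.null(highpass)) {
    B <- highpass_basis(length(y), bold$tr, highpass)
    y <- as.numeric(project_out(matrix(y, ncol = 1), B))
    X <- project_out(X, B)
    n_basis <- qr(B)$rank
  } else {
    X <- cbind(X, intercept = 1)
    n_basis <- 0
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design rank-deficient after pruning; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qx, y)
  resid <- y - X %*% betas
  dof <- length(y) - qx$rank - n_basis
  if (dof <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(resid^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(
    list(betas = stats::setNames(as.numeric(betas), colnames(X)),
         se = sqrt(sigma2 * diag(xtx_inv)),
         xtx_inv = xtx_inv, sigma2 = sigma2, dof = dof,
         colnames = colnames(X)),
    class = "session_fit"
  )
}

#' Contrast of a fitted session GLM
#'
#' `t = c'beta / sqrt(c' (X'X)^-1 c * sigma^2)`, two-tailed p.
#'
#' @param fit A `session_fit`.
#' @param weights Named numeric vector of contrast weights; columns not
#'   named get weight 0. Unnamed vectors must match the column count.
#' @param name Optional contrast label.
#' @return A list of class `glm_contrast`: `effect`, `se`, `t`, `p`,
#'   `dof`, `variance`.
#' @export
contrast <- function(fit, weights, name = NULL) {
  stopifnot(inherits(fit, "session_fit"))
  k <- length(fit$colnames)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), fit$colnames)
    if (length(unknown) > 0) {
      stop("contrast names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    w <- stats::setNames(numeric(k), fit$colnames)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != k) {
      stop("contrast length ", length(weights), " != ", k, " columns",
           call. = FALSE)
    }
    w <- weights
  }
  effect <- sum(w * fit$betas)
  variance <- as.numeric(t(w) %*% fit$xtx_inv %*% w) * fit$sigma2
  se <- sqrt(variance)
  t_stat <- effect / se
  p <- 2 * stats::pt(-abs(t_stat), df = fit$dof)
  structure(list(name = name, effect = effect, se = se, variance = variance,
                 t = t_stat, p = p, dof = fit$dof),
            class = "glm_contrast")
}

#' Fixed-effects combination of session-level effects
#'
#' Inverse-variance weighted average of per-session effect estimates; a
#' single session passes through with its own variance.
#'
#' @param effects Session effect estimates.
#' @param variances Their sampling variances (> 0).
#' @return List with `effect`, `variance`, `se`, `n_sessions`.
#' @export
fixed_effects <- function(effects, variances) {
  stopifnot(length(effects) == length(variances), all(variances > 0))
  w <- 1 / variances
  est <- sum(w * effects) / sum(w)
  v <- 1 / sum(w)
  list(effect = est, variance = v, se = sqrt(v), n_sessions = length(effects))
}

#' Group-level one-sample t-test over subject effects
#'
#' Two-tailed one-sample t across per-subject (fixed-effects combined)
#' estimates - the group stage used here in place of a mixed-effects
#' model.
#'
#' @param effects One estimate per subject (>= 2 subjects).
#' @param mu Null value (default 0).
#' @return List with `t`, `p`, `dof`, `mean`.
#' @export
group_ttest <- function(effects, mu = 0) {
  if (length(effects) < 2) stop("need >= 2 subjects", call. = FALSE)
  tt <- stats::t.test(effects, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       dof = unname(tt$parameter), mean = mean(effects))
}

#' Joint GLM of signed and absolute value difference
#'
#' Enters the normalized signed chosen-unchosen difference and the
#' normalized absolute difference as simultaneous parametric modulators on
#' the decision events (possible because the two are sufficiently
#' decorrelated); refuses with a diagnostic when their correlation exceeds
#' `cor_threshold`.
#'
#' @param trials Session data frame.
#' @param values Per-trial chosen/unchosen values (rows aligned).
#' @param bold A [bold_series()].
#' @param hrf An [gamma_hrf()] kernel.
#' @param cor_threshold Maximum tolerated |correlation| (default 0.9).
#' @param highpass Passed to [fit_glm_session()].
#' @return List with `beta_signed`, `beta_abs`, their `se_*` and
#'   `variance_*`, `regressor_cor`, `dof` and the full `fit`.
#' @export
signed_vs_absolute <- function(trials, values, bold, hrf = gamma_hrf(),
                               cor_threshold = 0.9, highpass = 100) {
  cs <- cs_chosen_trials(trials)
  d_raw <- values$chosen[cs] - values$unchosen[cs]
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  signed <- zs(d_raw)
  absv <- zs(abs(d_raw))
  r <- stats::cor(signed, absv)
  if (abs(r) >= cor_threshold) {
    stop(sprintf(
      "signed and absolute difference regressors too collinear (r = %.3f >= %.2f)",
      r, cor_threshold), call. = FALSE)
  }
  tr <- bold$tr
  n_volumes <- bold$n_volumes
  X <- cbind(
    cue = event_column(trials$t_cue[cs], 1, hrf, tr, n_volumes),
    cue_x_signed = event_column(trials$t_cue[cs], signed, hrf, tr, n_volumes),
    cue_x_abs = event_column(trials$t_cue[cs], absv, hrf, tr, n_volumes),
    outcome = event_column(trials$t_outcome[cs], 1, hrf, tr, n_volumes)
  )
  if (any(!cs)) {
    X <- cbind(X,
               cue_other = event_column(trials$t_cue[!cs], 1, hrf, tr, n_volumes),
               out_other = event_column(trials$t_outcome[!cs], 1, hrf, tr, n_volumes))
  }
  pruned <- drop_empty_columns(X, keep_warning = FALSE)
  design <- design_matrix(pruned$X, unconvolved = character(0),
                          dropped = pruned$dropped)
  fit <- fit_glm_session(bold, design, highpass = highpass)
  cs_signed <- contrast(fit, c(cue_x_signed = 1))
  cs_abs <- contrast(fit, c(cue_x_abs = 1))
  list(beta_signed = cs_signed$effect, se_signed = cs_signed$se,
       variance_signed = cs_signed$variance,
       beta_abs = cs_abs$effect, se_abs = cs_abs$se,
       variance_abs = cs_abs$variance,
       regressor_cor = r, dof = fit$dof, fit = fit)
}
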