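#' One-sample test of choice percentages against chance
#'
#' Two-tailed one-sample t-test of per-subject percentages against 50%.
#' When every subject has the identical percentage the t statistic is
#' undefined (zero variance); the result is then flagged `degenerate` with
#' `t` and `p` set to `NA` rather than erroring, since ceiling performance
#' across subjects is a legitimate outcome.
#'
#' @param percents Per-subject percentages (>= 2 subjects), each in
#'   \[0, 100\].
#' @param chance Null value (default 50).
#' @return List with `t`, `p`, `dof`, `mean`, `degenerate`.
#' @export
test_vs_chance <- function(percents, chance = 50) {
  if (length(percents) < 2) stop("need >= 2 subjects", call. = FALSE)
  if (any(percents < 0 | percents > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  if (stats::sd(percents) == 0) {
    return(list(t = NA_real_, p = NA_real_, dof = length(percents) - 1,
                mean = mean(percents), degenerate = TRUE))
  }
  tt <- stats::t.test(percents, mu = chance)
  list(t = unname(tt$statistic), p = tt$p.value,
       dof = unname(tt$parameter), mean = mean(percents), degenerate = FALSE)
}

#' Reaction-time regression on value sum and value difference
#'
#' Per session, OLS of RT on the sum and the (chosen - unchosen) difference
#' of the option values; session betas are averaged within subject and each
#' coefficient is tested against zero across subjects with a two-tailed
#' one-sample t-test. Faster responses on high-value and easy trials show
#' up as negative coefficients.
#'
#' @param trials Data frame with columns `subject`, `session`, `rt_ms`,
#'   `v_chosen`, `v_unchosen` (choice trials).
#' @return List with `subject_betas` (subject x c(b_sum, b_diff)),
#'   `group_sum` and `group_diff` (each a `t`/`p`/`dof`/`mean` list).
#' @export
rt_regression <- function(trials) {
  need <- c("subject", "session", "rt_ms", "v_chosen", "v_unchosen")
  stopifnot(all(need %in% names(trials)))
  key <- interaction(trials$subject, trials$session, drop = TRUE)
  fits <- lapply(split(trials, key), function(tr) {
    vsum <- tr$v_chosen + tr$v_unchosen
    vdiff <- tr$v_chosen - tr$v_unchosen
    if (stats::sd(vsum) == 0 || stats::sd(vdiff) == 0) {
      stop("constant value regressor within a session", call. = FALSE)
    }
    co <- stats::coef(stats::lm(tr$rt_ms ~ vsum + vdiff))
    c(subject = tr$subject[1], b_sum = unname(co["vsum"]),
      b_diff = unname(co["vdiff"]))
  })
  df <- do.call(rbind.data.frame, fits)
  names(df) <- c("subject", "b_sum", "b_diff")
  df$b_sum <- as.numeric(df$b_sum)
  df$b_diff <- as.numeric(df$b_diff)
  subj <- stats::aggregate(cbind(b_sum, b_diff) ~ subject, df, mean)
  one_t <- function(x) {
    if (length(x) < 2) return(NULL)  # group stage needs >= 2 subjects
    tt <- stats::t.test(x)
    list(t = unname(tt$statistic), p = tt$p.value,
         dof = unname(tt$parameter), mean = mean(x))
  }
  list(subject_betas = subj,
       group_sum = one_t(subj$b_sum),
       group_diff = one_t(subj$b_diff))
}

#' Repeated-measures ANOVA (classical sums of squares)
#'
#' Univariate repeated-measures decomposition with subject as a random
#' factor, fitted through `stats::aov` with the appropriate `Error`
#' strata; supports within-subject factors and one optional
#' between-subjects factor (subjects nested in groups). The design must be
#' complete and balanced - one mean per subject x within-cell - otherwise
#' an error lists the offending cells. An optional square-root transform is
#' applied to the response before decomposition. Degrees of freedom are
#' reported uncorrected (no sphericity correction); a warning notes this
#' whenever a within factor has more than two levels.
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor names.
#' @param between Optional between-subjects factor name.
#' @param subject Subject identifier column (default `"subject"`).
#' @param transform `"identity"` (default) or `"sqrt"`.
#' @return A `data.frame` of class `anova_result` with columns `effect`,
#'   `df1`, `df2`, `F`, `p`, `transform`.
#' @export
rm_anova <- function(data, dv, within, between = NULL,
                     subject = "subject",
                     transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  data <- as.data.frame(data)
  cols <- c(dv, within, between, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (f in c(within, between, subject)) data[[f]] <- factor(data[[f]])
  cell <- interaction(data[c(subject, within)], drop = FALSE)
  counts <- table(cell)
  if (any(counts != 1)) {
    bad <- names(counts)[counts != 1]
    stop("design not complete/balanced (one observation per subject x ",
         "within-cell required); offending cell(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  y <- data[[dv]]
  if (transform == "sqrt") {
    if (any(y < 0)) stop("square-root transform needs non-negative values",
                         call. = FALSE)
    data[[dv]] <- sqrt(y)
  }
  if (any(vapply(within, function(f) nlevels(data[[f]]) > 2, logical(1)))) {
    warning("within factor with > 2 levels: F tests assume sphericity ",
            "(no correction applied)", call. = FALSE)
  }
  w_term <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) w_term else paste0(between, "*", w_term)
  form <- stats::as.formula(
    paste0(dv, " ~ ", fixed, " + Error(", subject, "/(", w_term, "))"))
  fit <- stats::aov(form, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    if (length(resid_row) == 0) next
    df2 <- tab$Df[resid_row]
    for (i in seq_len(nrow(tab))) {
      if (i == resid_row || is.na(tab$`F value`[i])) next
      out[[length(out) + 1]] <- data.frame(
        effect = rn[i], df1 = tab$Df[i], df2 = df2,
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
        transform = transform, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("anova_result", class(res))
  res
}
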