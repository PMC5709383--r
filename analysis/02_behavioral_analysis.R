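#!/usr/bin/env Rscript
# Behavioral analyses of the simulated cohorts: empirical subjective
# values per animal, choice frequencies against chance, reaction-time
# regressions on value sum/difference, and the group x decision
# repeated-measures ANOVA contrasting control and lesion-like agents.

suppressPackageStartupMessages(library(valuefmri))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_events\\.tsv$", full.names = TRUE)
  lapply(files, function(f) {
    tr <- read_session_events(f)
    id <- regmatches(basename(f), regexec("sub-([0-9]+)_ses-([0-9]+)",
                                          basename(f)))[[1]]
    tr$subject <- as.integer(id[2])
    tr$session <- as.integer(id[3])
    tr
  })
}

control <- read_cohort("results/behavior/control")
lesion <- read_cohort("results/behavior/lesion")

# --- empirical value tables per animal -------------------------------------
value_rows <- list()
for (grp in c("control", "lesion")) {
  sessions <- if (grp == "control") control else lesion
  stacked <- do.call(rbind, sessions)
  for (s in unique(stacked$subject)) {
    vt <- stimulus_value_table(stacked[stacked$subject == s, ])
    value_rows[[length(value_rows) + 1]] <- data.frame(
      group = grp, subject = s, t(as.numeric(vt[c("HV", "CV", "LV")])))
  }
}
values_df <- do.call(rbind, value_rows)
names(values_df)[3:5] <- c("HV", "CV", "LV")
write.csv(values_df, "results/tables/empirical_values.csv", row.names = FALSE)

ctrl_vals <- values_df[values_df$group == "control", ]
cat(sprintf("control value ordering HV > CV > LV holds in %d/%d animals\n",
            sum(ctrl_vals$HV > ctrl_vals$CV & ctrl_vals$CV > ctrl_vals$LV),
            nrow(ctrl_vals)))

# --- choice frequency vs chance on CS+ vs CS+ trials -----------------------
pct_better <- function(sessions) {
  vapply(split(do.call(rbind, sessions),
               do.call(rbind, sessions)$subject), function(tr) {
    ch <- tr$trial_type == "choice_cs_plus"
    100 * mean(tr$v_chosen[ch] >= tr$v_unchosen[ch])
  }, numeric(1))
}
pc <- pct_better(control)
chance <- test_vs_chance(pc)
cat(sprintf("control %% choosing higher-valued CS+: mean %.1f%%, t = %.2f, p = %.2g\n",
            chance$mean, chance$t, chance$p))

# --- RT ~ value sum + value difference -------------------------------------
rt_in <- do.call(rbind, lapply(control, function(tr) {
  ch <- grepl("^choice", tr$trial_type)
  data.frame(subject = tr$subject[ch], session = tr$session[ch],
             rt_ms = tr$rt_ms[ch], v_chosen = tr$v_chosen[ch],
             v_unchosen = tr$v_unchosen[ch])
}))
rt_res <- rt_regression(rt_in)
write.csv(rt_res$subject_betas, "results/tables/rt_betas.csv",
          row.names = FALSE)
cat(sprintf("RT on value sum: mean %.1f ms/unit (t = %.2f, p = %.3g)\n",
            rt_res$group_sum$mean, rt_res$group_sum$t, rt_res$group_sum$p))
cat(sprintf("RT on value difference: mean %.1f ms/unit (t = %.2f, p = %.3g)\n",
            rt_res$group_diff$mean, rt_res$group_diff$t, rt_res$group_diff$p))

# --- group x day x decision repeated-measures ANOVA ------------------------
pct_cell <- function(tr, dec) {
  sel <- switch(dec,
    hv_cv = tr$trial_type == "choice_cs_plus" &
      ((tr$offered_1 == "HV" & tr$offered_2 == "CV") |
         (tr$offered_1 == "CV" & tr$offered_2 == "HV")),
    hv_lv = tr$trial_type == "choice_cs_plus" &
      ((tr$offered_1 == "HV" & tr$offered_2 == "LV") |
         (tr$offered_1 == "LV" & tr$offered_2 == "HV")),
    cv_lv = tr$trial_type == "choice_cs_plus" &
      ((tr$offered_1 == "CV" & tr$offered_2 == "LV") |
         (tr$offered_1 == "LV" & tr$offered_2 == "CV")))
  first <- substr(toupper(dec), 1, 2)
  100 * mean(tr$choice[sel] == first)
}
anova_rows <- list()
for (grp in c("control", "lesion")) {
  sessions <- if (grp == "control") control else lesion
  for (tr in sessions) {
    for (dec in c("hv_cv", "hv_lv", "cv_lv")) {
      anova_rows[[length(anova_rows) + 1]] <- data.frame(
        subject = paste(grp, tr$subject[1]), group = grp,
        day = tr$session[1], decision = dec, pct = pct_cell(tr, dec))
    }
  }
}
anova_df <- do.call(rbind, anova_rows)
tab <- suppressWarnings(
  rm_anova(anova_df, dv = "pct", within = c("day", "decision"),
           between = "group"))
write.csv(tab, "results/tables/group_decision_anova.csv", row.names = FALSE)
ix <- tab$effect == "group:decision"
cat(sprintf("group x decision interaction: F(%d, %d) = %.2f, p = %.3g\n",
            tab$df1[ix], tab$df2[ix], tab$F[ix], tab$p[ix]))
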