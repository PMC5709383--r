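#!/usr/bin/env Rscript
# Decision-locked ROI time-course analysis: epoch and upsample the
# simulated series, estimate per-timepoint value-difference betas, select
# peaks by within-animal leave-one-session-out, test across animals, and
# run the spatial analog plus the trial-peak factorial analysis.

suppressPackageStartupMessages(library(valuefmri))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
h <- gamma_hrf()
tr_s <- 2.28

simulate_session_betas <- function(subject, session) {
  seed <- 40000 + 100 * subject + session
  tr <- generate_lessismore_session(lessismore_config(n_trials = 60,
                                                      seed = seed),
                                    subjective_agent(temperature = 0.25))
  vt <- stimulus_value_table(tr)
  vals <- build_trial_values(tr, vt)
  keep <- which(tr$choice %in% c("HV", "LV", "CV"))
  sim_tr <- tr[keep, ]
  sim_tr$v_chosen <- vals$chosen[keep]
  sim_tr$v_unchosen <- vals$unchosen[keep]
  n_vol <- ceiling((max(tr$t_outcome) + 16) / tr_s) + 1
  bold <- generate_linear_roi(sim_tr, list(decision = 1, diff = -0.6),
                              h, n_volumes = n_vol, seed = seed + 1)
  ep <- epoch_upsample(bold, sim_tr$t_cue, window = c(-2, 14), step = 0.25)
  mods <- attr(bold, "modulators")
  tb <- timepoint_regression(ep, data.frame(diff_z = mods$diff_z[ep$kept]))
  tb$betas[, "diff_z"]
}

subjects <- 1:4
sessions <- 1:4
subject_mats <- lapply(subjects, function(s) {
  do.call(rbind, lapply(sessions, function(k) simulate_session_betas(s, k)))
})

loo <- loo_group_stat(subject_mats)
cat(sprintf("temporal LOO: subject values %s\n",
            paste(sprintf("%.3f", loo$subject_values), collapse = ", ")))
cat(sprintf("temporal LOO group test: t(%d) = %.2f, p = %.3g\n",
            loo$dof, loo$t, loo$p))

# spatial analog on the voxel grid: per-session voxel effect maps,
# within-animal LOO voxel selection
session_voxel_map <- function(subject, session) {
  seed <- 50000 + 100 * subject + session
  tr <- generate_lessismore_session(lessismore_config(n_trials = 40,
                                                      seed = seed),
                                    subjective_agent(temperature = 0.25))
  vt <- stimulus_value_table(tr)
  vals <- build_trial_values(tr, vt)
  keep <- which(tr$choice %in% c("HV", "LV", "CV"))
  sim_tr <- tr[keep, ]
  sim_tr$v_chosen <- vals$chosen[keep]
  sim_tr$v_unchosen <- vals$unchosen[keep]
  grid <- generate_linear_grid(sim_tr, list(decision = 1, diff = -0.6), h,
                               dim = c(5, 5, 5), center = c(3, 3, 3),
                               seed = seed + 1)
  mods <- normalize_regressors(sim_tr$v_chosen, sim_tr$v_unchosen)
  nt <- dim(grid$data)[4]
  vapply(seq_len(5 * 5 * 5), function(v) {
    idx <- arrayInd(v, c(5, 5, 5))
    series <- bold_series(grid$data[idx[1], idx[2], idx[3], ], tr_s)
    ep <- epoch_upsample(series, sim_tr$t_cue, window = c(0, 8), step = 0.5)
    tb <- timepoint_regression(ep, data.frame(diff_z = mods$diff_z[ep$kept]))
    tb$betas[which.max(abs(tb$betas[, "diff_z"])), "diff_z"]
  }, numeric(1))
}
spatial_mats <- lapply(1:4, function(s) {
  do.call(rbind, lapply(1:3, function(k) session_voxel_map(s, k)))
})
sp <- loo_group_stat(spatial_mats)
cat(sprintf("spatial LOO group test: t(%d) = %.2f, p = %.3g\n",
            sp$dof, sp$t, sp$p))

# trial-peak factorial analysis (1.5-6.5 s window) on choice trials
set.seed(60001)
rows <- list()
for (s in subjects) {
  tr <- generate_lessismore_session(lessismore_config(n_trials = 120,
                                                      seed = 60010 + s),
                                    subjective_agent(temperature = 0.25))
  # the factorial cells: chosen value (HV, CV) x unchosen value (UNREW, LV)
  unchosen_all <- ifelse(tr$choice == tr$offered_1, tr$offered_2,
                         tr$offered_1)
  sel <- which(tr$choice %in% c("HV", "CV") &
                 unchosen_all %in% c("UNREW", "LV"))
  sim_tr <- tr[sel, ]
  n_vol <- ceiling((max(tr$t_outcome) + 16) / tr_s) + 1
  bold <- generate_linear_roi(sim_tr,
                              list(decision = 1, diff = -0.6, sum = 0),
                              h, n_volumes = n_vol, seed = 60020 + s)
  ep <- epoch_upsample(bold, sim_tr$t_cue, window = c(-2, 8), step = 0.25)
  kept <- sim_tr[ep$kept, ]
  unchosen_lab <- ifelse(kept$choice == kept$offered_1, kept$offered_2,
                         kept$offered_1)
  pk <- trial_peak_analysis(
    ep, data.frame(chosen = kept$choice, unchosen = unchosen_lab))
  cells <- do.call(rbind, strsplit(names(pk$cell_means), " vs "))
  rows[[s]] <- data.frame(subject = s, chosen = cells[, 1],
                          unchosen = cells[, 2],
                          mean_peak = as.numeric(pk$cell_means))
}
peaks_df <- do.call(rbind, rows)
write.csv(peaks_df, "results/tables/trial_peak_cells.csv", row.names = FALSE)
agg <- aggregate(mean_peak ~ chosen + unchosen, peaks_df, mean)
cat("mean trial-peak activity per chosen x unchosen cell:\n")
print(agg)
tab <- rm_anova(peaks_df, dv = "mean_peak", within = c("chosen", "unchosen"),
                subject = "subject")
ix_c <- tab$effect == "chosen"
ix_u <- tab$effect == "unchosen"
cat(sprintf("chosen value: F(%d, %d) = %.2f, p = %.3g; unchosen value: F(%d, %d) = %.2f, p = %.3g\n",
            tab$df1[ix_c], tab$df2[ix_c], tab$F[ix_c], tab$p[ix_c],
            tab$df1[ix_u], tab$df2[ix_u], tab$F[ix_u], tab$p[ix_u]))
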