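#!/usr/bin/env Rscript
# Fit the Rescorla-Wagner/softmax model session-by-session to the
# simulated reversal cohort and summarize how well the generating
# parameters (alpha = 0.3, T = 0.2) are recovered.

suppressPackageStartupMessages(library(valuefmri))

cfg <- run_config("reversal", n_subjects = 4, n_sessions = 5, seed = 20003,
                  agent_args = list(alpha = 0.3, temp = 0.2),
                  out_dir = "results/behavior/reversal")
fits <- run_fit_rl(cfg)

cat(sprintf("fitted %d sessions\n", nrow(fits)))
cat(sprintf("alpha: median %.3f (true 0.30), MAD of error %.3f\n",
            median(fits$alpha_hat), median(abs(fits$alpha_hat - 0.3))))
cat(sprintf("T:     median %.3f (true 0.20), MAD of error %.3f\n",
            median(fits$temp_hat), median(abs(fits$temp_hat - 0.2))))
cat(sprintf("NLL per trial: %.3f (chance would be log 2 = %.3f)\n",
            mean(fits$nll / fits$n_trials), log(2)))
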