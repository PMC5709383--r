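# valuefmri

Synthetic pipeline for value-guided choice behavior and model-based fMRI
in the macaque.

When a monkey chooses between reward-predicting stimuli, aggregate
activity in ventromedial prefrontal cortex (vmPFC) tracks the *comparison*
between options: it falls as the chosen−unchosen value difference grows
(easy decisions), rises when options are close — and that sign can flip if
the circuit holds the winning representation after the decision instead of
letting it decay. Studying such signals requires a chain of machinery:
behavioral task schedules, learning-model fits, subjective-value
estimation from choices, HRF-convolved GLMs with parametric value
regressors, and peak selection that avoids circular inference. `valuefmri`
implements that entire chain over synthetic data with known ground truth,
so every procedure can be validated — effect recovery, error-rate
calibration, selection bias — before it is trusted on real data. It is
aimed at researchers in decision neuroscience and model-based fMRI who
want an auditable reference implementation of these analyses.

The core models:

* **Rescorla–Wagner / softmax** — values update by the delta rule,
  V ← V + α(r − V) for the chosen stimulus only, and choices follow
  P ∝ exp(V/T) over the offered pair. Session parameters (α, T) are fitted
  by minimizing the negative log likelihood L = −Σ log P(cₜ) with bounded
  quasi-Newton optimization and Latin-hypercube restarts.
* **Frequency-based subjective values** — a stimulus's value is the
  offer-weighted proportion of times it was chosen across presentation
  contexts, algebraically total-chosen / total-offered; per-trial chosen,
  unchosen, and difference regressors are z-scored independently.
* **BOLD forward models** — event amplitudes (linear in the normalized
  value sum and difference) or two-pool attractor dynamics (recurrent
  excitation, mutual inhibition, threshold crossing) convolved with the
  fast macaque HRF, a gamma kernel with 3 s mean and 1.5 s SD (shape 4,
  scale 0.75 s), sampled at TR = 2.28 s.
* **GLM engine and time-course analysis** — 24-regressor condition GLM and
  10-regressor parametric GLM, OLS after identical 100-s high-pass
  filtering of data and design, fixed-effects combination within subject,
  decision-locked epoching with 0.25 s upsampling, per-timepoint
  regressions, and leave-one-out peak selection with a calibrated
  across-subject test.

## Worked example

```r
library(valuefmri)

# one session of the single/choice task: 120 trials, 75% single-option
session <- generate_lessismore_session(lessismore_config(seed = 42),
                                       subjective_agent())
table(session$trial_type)
#> choice_cs_minus  choice_cs_plus          single
#>              15              15              90

# empirical subjective values recover the "less-is-more" ordering
round(stimulus_value_table(session)[c("HV", "CV", "LV")], 3)
#>    HV    CV    LV
#> 0.956 0.911 0.756

# a reversal session, fitted with the Rescorla-Wagner/softmax model
rev <- generate_reversal_session(reversal_config(seed = 42),
                                 rl_params(alpha = 0.3, temp = 0.2))
fit_rl_session(as_choice_sequence(rev), seed = 1)
#> RW/softmax fit: alpha = 0.293, T = 0.170, NLL = 79.433 (200 trials, 10 restarts)
reoffer_rate(rev)   # 2 of 3 stimuli drawn per trial -> ~66.7%
#> 66.8

# forward-model BOLD with a planted negative value-difference effect,
# recovered by the parametric GLM
h <- gamma_hrf()
vals <- data.frame(trial = rev$trial, chosen = rev$v_chosen,
                   unchosen = rev$v_unchosen)
n_vol <- ceiling((max(rev$t_outcome) + 16) / 2.28) + 1
bold <- generate_linear_roi(rev, list(decision = 1, diff = -0.8), h,
                            n_volumes = n_vol, seed = 7)
des <- build_glm2(rev, vals, h, n_volumes = n_vol)
contrast(fit_glm_session(bold, des), c(cue_cs_x_diff = 1))
#> value-difference beta: -0.773 (t = -5.00, p = 7.2e-07)
```

The HV > CV > LV ordering is the "less-is-more" pattern: the compound
option (both juices) is valued below the better juice alone. The fitted α
and T sit near the generating values (0.3, 0.2), the re-offer rate matches
the 2/3 implied by drawing two of three stimuli uniformly, and the GLM
recovers the planted negative value-difference amplitude.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on simulated cohorts and write tables under `results/`:

1. `01_simulate_behavior.R` — control, lesion-like and reversal cohorts
2. `02_behavioral_analysis.R` — value tables, choice vs chance, RT
   regressions, group × decision repeated-measures ANOVA
3. `03_fit_rl.R` — session-wise learning-model fits and recovery summary
4. `04_glm_value_signals.R` — parametric GLM, fixed effects, group test,
   signed vs absolute value difference
5. `05_timecourse_loo.R` — epoched time courses, temporal and spatial
   leave-one-out peak tests, trial-peak factorial analysis
6. `06_attractor_signflip.R` — decay vs sustain regimes of the attractor
   network and the resulting sign flip of the value-difference beta

Run them in order with `Rscript analysis/01_simulate_behavior.R` etc.

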