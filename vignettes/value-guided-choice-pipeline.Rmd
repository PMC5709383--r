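---
title: "Simulating value-guided choice and its vmPFC signature: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating value-guided choice and its vmPFC signature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuefmri)
```

`valuefmri` is a synthetic test bed for the analysis chain used to study
value comparison in macaque ventromedial prefrontal cortex (vmPFC): task
simulators, learning-model fits, subjective-value estimation, BOLD forward
models, a parametric GLM engine, and decision-locked time-course analyses
with leave-one-out peak selection. No animal data ship with the package;
every analysis runs on data the package itself generates, which is the
point — each statistical procedure can be audited against ground truth.

## The two tasks

**Single/choice ("less-is-more") task.** A 120-trial session mixes 75%
single-option trials (one CS+ shown; the animal may take it or skip via the
blank side of the screen) with 25% choice trials, split between CS+ vs CS-
and CS+ vs CS+ pairs. Counts are allocated deterministically and shuffled,
so a 120-trial session has exactly 90 single-option and 30 choice trials;
for non-integral products the single-option count is rounded to nearest and
the remainder goes to choice trials. The split of choice trials between
CS+/CS- and CS+/CS+ pairs is exposed as `p_csminus_of_choice` (default
0.5, i.e. 15 + 15 trials) because the two subsets must jointly fill the
30-trial share of the session.

Agents hold subjective values for the high-value (HV) and low-value (LV)
juices and derive the compound option's value from a bias parameter:
`v_CV = cv_bias * mean(v_HV, v_LV) + (1 - cv_bias) * (v_HV + v_LV)`. With
`cv_bias = 1` (the control default) valuation averages and the
"less-is-more" ordering HV > CV > LV emerges; `cv_bias = 0` values the
compound objectively as the sum. Choice is softmax with temperature `T` in
value units; skipping a single-option trial is modeled as a softmax choice
between the option's value and a skip value of 0. Reaction times are
linear in the sum and difference of the chosen and unchosen values with
negative slopes, Gaussian noise, and a 250 ms floor (truncation, not
resampling).

**Three-option reversal task.** Three stimuli carry drifting reward
probabilities — a reflected Gaussian random walk (starts uniform on
[0.2, 0.8], per-trial step SD 0.03, reflecting bounds [0.1, 0.9]); the
drift parameters are the package's own choice of a schedule that forces
continual relearning while keeping outcomes informative. Two of the three
stimuli are drawn uniformly without replacement each trial, which makes
the probability that any designated stimulus — in particular the one just
chosen — reappears on the next trial exactly 2/3. A Rescorla-Wagner agent
chooses between the offered pair.

## Learning model and likelihood

Values update by the delta rule, `V <- V + alpha * (r - V)`, for the chosen
stimulus only; unchosen and unoffered stimuli carry their values forward.
Choice probabilities are softmax, `P ∝ exp(V / T)`. The likelihood of a
session is the product of the probabilities of the observed choices under
a forward pass (probabilities first, update after), and fitting minimizes
`L = -sum(log P)` with L-BFGS-B inside the box alpha ∈ [0.01, 0.99],
T ∈ [0.01, 10], restarted from a Latin-hypercube sample (10 starts by
default; temperatures are sampled log-uniformly since the plausible range
spans decades). The reported optimum is never worse than any evaluated
start. Initial values are 0.5 for every stimulus — the uninformative
midpoint of the 0/1 reward range.

One genuinely open choice: whether the softmax denominator runs over all
three stimuli or only the two offered. We normalize over the offered pair,
because only those actions are available on a trial; the three-option
normalization is available via `all_options = TRUE` in `session_nll()`,
and we assert nothing about which convention any particular dataset used.
Parameter recovery at the defaults (200 trials, alpha = 0.3, T = 0.2) has
median absolute errors well below 0.1 and 0.05 respectively.

## Empirical subjective values

For experiment-2-style data, each stimulus's value is frequency-based: in
every context in which it was offered (vs the blank side, vs a CS-, vs
each other CS+), the proportion of offers on which it was chosen is
weighted by the number of offers in that context, summed, and divided by
the total number of offers. That weighted sum is algebraically
total-chosen / total-offered, and the test suite enforces the equivalence
property-wise. Values live on the [0, 1] proportion scale throughout;
percent enters only at presentation boundaries.

Per-trial regressors take the value of the option taken and the option
rejected with no reordering; on single-option trials the rejected action
is skipping, valued 0. Normalization z-scores the chosen values, the
unchosen values, and their difference *separately* per session — the
normalized difference is the z-score of the raw difference, not the
difference of z-scores — so that betas are comparable across sessions with
different value distributions. A session where the value sum is constant
yields no sum modulator (it is reported as `NULL` rather than fabricated).

## BOLD forward models

The hemodynamic kernel is a gamma density with 3 s mean and 1.5 s spread,
i.e. shape 4 and scale 0.75 s — the fast macaque response. "Spread" is
interpreted as the standard deviation; a full-width-at-half-maximum
reading is available via `width_type = "fwhm"`. The kernel is normalized
to unit sum, so convolution preserves event amplitude in the integral
sense; a unit event has a sampled peak of about 0.07. Noise defaults
(AR(1) with coefficient 0.3 and stationary SD 0.05, white SD 0.025,
optional slow cosine drift with a period above the high-pass cutoff) are
scaled to that response so the shipped simulations look like averaged ROI
data: clear mean responses, noisy single trials.

Two generators produce decision-locked signals:

* **Linear amplitude model** — each decision event evokes
  `b0 + b_diff * diff_z + b_sum * sum_z`; each outcome event `b_out`
  (plus an optional chosen-value modulation at outcome, exposed for
  exploring protracted/reactivated value signals but asserted nowhere).
  With `b_diff < 0` the ROI mirrors the macaque finding: activity grows as
  decisions get harder. A voxel-grid variant places the effect in a
  3-voxel-radius Gaussian blob for the spatial selection analyses.
* **Two-pool attractor model** — a reduced rate model: two rectified,
  saturating accumulators with self-excitation, mutual inhibition, leak,
  value-proportional input and diffusion noise; a decision is the first
  threshold crossing. Parameters (self-excitation 3, cross-inhibition 4,
  leak 2.5 s^-1, input gain 0.5, baseline drive 0.4, noise 0.15) were
  chosen once so the median decision time is about 1 s at large value
  differences and shrinks as the difference grows. After the decision the
  *regime* matters: under `"decay"` inputs and recurrence are withdrawn
  and activity relaxes, so integrated activity mostly reflects
  deliberation time and the fitted value-difference beta is negative;
  under `"sustain"` the winner's recurrence holds it at its attractor
  until trial end, so easy (fast) decisions accumulate more activity and
  the fitted beta rises — the sign flip that distinguishes a
  comparison-dominated from a maintenance-dominated aggregate signal. The
  suite asserts the sign and the ordering, not a particular magnitude.
  Ties under zero noise (both pools crossing on one step) break toward the
  pool with higher activity, then toward pool 1; with symmetric
  sub-threshold drive and no noise the race never resolves and the trial
  is flagged undecided rather than forced.

## GLM engine

The condition GLM has 24 columns: cue- and outcome-locked regressors for
nine decision-type x choice conditions plus a discarded-trials pair, and
four response regressors (left/right, HRF-convolved and unconvolved spike
versions; the spikes absorb motion-like artifacts at response time). The
exact nine-condition mapping for the synthetic task is documented in
`condition_label()` and is deliberately provisional — it covers every cell
the simulated task can produce. The parametric GLM has ten columns: four
event regressors (CS+-chosen cue/outcome, no-CS+ cue/outcome), the two
value modulators on the CS+-chosen cue (normalized sum and difference,
mean-centered by construction), and the same four response regressors.
Events are deltas (zero duration); conditions absent from a session drop
their empty columns with a warning and a record, so contrast weights can
be renormalized downstream.

Fitting is OLS after both data and design pass the identical high-pass
filter, a projection onto the complement of a low-frequency basis with
100 s cutoff. The basis uses sine/cosine pairs at *half-harmonic* spacing
rather than a truncated DCT: a drift whose period is not a harmonic of the
record length leaks through a standard-density DCT (about 17% of a 200 s
cosine survives), whereas the denser trigonometric span removes it
essentially completely while attenuating 20 s-period signal by under 2%.
Degrees of freedom subtract the basis rank as well as the design rank.
Contrast t statistics are two-tailed. Sessions combine within subject by
inverse-variance (fixed-effects) weighting; the group stage is a one-sample
t-test across subject estimates — a deliberate, simpler stand-in for a
mixed-effects model, adequate for synthetic cohorts where between-subject
variance is controlled. With four subjects its power is limited: effects
around half a between-subject SD are usually missed, and the suite
demonstrates detection at clearly separated effects instead.

Calibration simulations (CI coverage of planted betas, type-I error of
contrasts) use white measurement noise, matching the error model whose
confidence statements are being audited; the AR(1)+drift noise remains the
default for realistic-looking series. Coverage sits at 95% and the null
rejection rate at 5% within Monte-Carlo error.

The signed and absolute value-difference modulators can be fitted jointly
only when sufficiently decorrelated; the function reports their
correlation and refuses above |r| = 0.9. In near-greedy sessions the
difference is almost always positive and |d| ≈ d, so this analysis is
meaningful mainly for reversal-style sessions where stochastic choice and
drifting values make the signed difference change sign.

## Time-course analysis and selection without circularity

ROI extraction averages voxels within a Euclidean sphere (radius 2 voxels
= 33 lattice voxels). Epochs are aligned to decision onset over -2 to
+14 s and upsampled to 0.25 s by linear interpolation (the method and rate
are our choice; linear interpolation is exact for linear signals and
introduces no ringing). No baseline correction is applied by default;
pre-event mean subtraction is available by option. At each timepoint, the
signal is regressed across trials on the normalized value regressors plus
an intercept, giving a beta ("effect size") time course per session.

Peak selection uses the leave-one-out rule: each held-out session's
read-out point is the extremum of the mean beta curve of the *other*
sessions. Because negative effects are expected, the default selects the
extremum of the absolute mean and records its sign ("maximum value" is
ambiguous for negative-going effects; the literal maximum remains
available). Two properties matter and the suite asserts both:

* a one-sample t directly across the held-out *session* values is still
  anticonservative under the null — each value is individually unbiased,
  but the values share their selection folds and are positively
  correlated, so session-level read-outs are reported but not treated as
  inference;
* the calibrated procedure is hierarchical, mirroring a
  several-animals-few-sessions design: select within subject, average the
  held-out values into one number per subject, and t-test across subjects
  (`loo_group_stat()`). Under a simulated null this test rejects at the
  nominal 5% while the circular alternative — one common peak chosen from
  the pooled data of every session, including the data being tested —
  rejects more than 40% of the time. The spatial version applies the same
  fold logic to per-session voxel maps.

The trial-peak analysis takes each trial's maximum between 1.5 and 6.5 s
after the cue, averages peaks per chosen-option x unchosen-option cell,
and feeds subject cell means into a repeated-measures ANOVA.

## Behavioral statistics

Choice percentages are tested against 50% with a two-tailed one-sample t
(raw percentages, untransformed); an all-identical input — ceiling
performance — returns a flagged degenerate result rather than an error.
RT regressions fit each session by OLS on value sum and difference,
average betas within subject, and t-test across subjects. The
repeated-measures ANOVA is the classical sums-of-squares decomposition via
`aov` error strata, with an optional square-root transform of the response
applied before decomposition and support for one between-subjects factor.
No sphericity correction is applied; a warning notes this whenever a
within factor has more than two levels, since the correction would alter
degrees of freedom but not the pipeline's structure.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; a single top-level seed
expands into per-stage seeds via `split_seed()` (seeded sampling without
replacement from the 31-bit range). Generators are bit-reproducible given
their seed, and `run_simulate()` manifests (config, seeds, file checksums)
are byte-identical across repeated runs of one configuration.

The shipped analyses use cohorts of 4 control and 2 lesion-like animals
with 4 sessions each for the single/choice task, 4 animals x 5 sessions
for the reversal task, 100-500 trials per regime for the attractor
comparison, and simulation counts of 100-1,000 replicates for the
calibration studies — sizes at which every Monte-Carlo check in the test
suite is stable while a full run of suite plus analyses completes in a
few minutes on one core.

## What the synthetic data do and do not establish

The generators reproduce the *structure* of the experiments — trial
allocation, option sets, drifting schedules, event timing, value-dependent
choice and RT, decision-locked BOLD with a negative value-difference
amplitude — with parameters either taken from the task descriptions or
chosen once as field-plausible defaults. They do not emulate real
measurement artifacts (motion, physiological noise, spatial smoothness of
real BOLD), satiety dynamics during devaluation (represented only as a
value-parameter change), training history, or inter-animal heterogeneity
beyond what the configs specify. Passing tests therefore certify that the
*procedures* are correct and calibrated on data with known ground truth —
recovery of planted effects, nominal error rates, unbiased selection — not
that any particular empirical effect size in real tissue is reproduced.
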