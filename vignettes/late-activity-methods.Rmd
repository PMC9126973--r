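---
title: "Models and methods: early and late activity in sensory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: early and late activity in sensory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latewave)
```

# The scientific setting

`latewave` analyses head-fixed rodent change-detection experiments in which a
continuous audiovisual stream occasionally changes — the orientation of a
drifting grating (visual trial) or the centre frequency of a harmonic complex
tone (auditory trial) — and the animal reports the change by licking a side
spout. Laminar extracellular recordings in primary visual cortex during such
tasks show two waves of activity: an early, bottom-up sensory transient
(roughly the first 200 ms after the change) and a late, report-related wave
that appears on hit trials only and precedes the first lick. The package
implements the full quantitative chain used to characterise these phenomena:

1. **Behaviour**: psychometric and multi-alternative signal-detection models
   of choices, plus session-quality filters and quantification of
   optogenetic-silencing effects.
2. **Single-neuron encoding**: a kernel-based Poisson regression of binned
   spike counts on task and behavioural variables with elastic-net
   regularisation, and explained-variance partitioning by predictor family.
3. **Single-neuron decoding**: time-resolved ROC discriminability with
   permutation tests, coder classification, population coding fractions and
   coding-onset estimates (with bootstrap), laminar maps, and the regression
   of coding onset on reaction time.
4. **Population statistics**: pairwise noise correlations aligned to the
   stimulus or the first lick, reaction-time-tertile decorrelation onsets,
   pre-photostimulation state contrasts, and random-forest decoding of
   grating orientation.
5. **A synthetic-session generator** that produces complete sessions
   (trials, choices, spikes, licks, pupil) with the statistical structure
   these analyses assume, retaining ground truth so every estimator can be
   validated by parameter recovery.

# Behavioural models

## Cumulative-normal psychometric function

The probability of responding at change magnitude $x$ is
$f(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\big((x - \mu)/\sigma\big)$,
with false-alarm rate $\gamma$, lapse rate $\lambda$, threshold $\mu$ and
slope $\sigma$. `fit_cumnorm()` maximises the binomial likelihood with a
bounded quasi-Newton optimiser and multiple restarts, and reports the
conventional saliency landmarks sub ($\mu-\sigma$), thr ($\mu$), sup
($\mu+\sigma$) and max.

## Multi-alternative detection model

Choices among *no-go*, *visual response* and *auditory response* are modelled
with a bivariate decision variable: independent standard-normal evidence on a
visual and an auditory axis, the stimulated modality adding its $d'$ to its
axis mean. The observer reports modality $m$ iff
$\Psi_m \ge c_m$ **and** $\Psi_m - c_m \ge \Psi_{o} - c_{o}$.
The source literature leaves the exact tie-breaking between the two
criterion-relative axes open; this rule is one consistent choice and is the
package's definition (documented here deliberately — `madc_rates()` is
cross-checked in the test suite against a brute-force Monte-Carlo simulation
of the same rule). Response probabilities are one-dimensional integrals,
$P(\text{respond } m) = \int_{c_m}^{\infty}
\phi(x-\mu_m)\,\Phi(x - c_m + c_o - \mu_o)\,dx$,
evaluated by 80-node Gauss–Legendre quadrature on $[c_m, \max(c_m,\mu_m)+8]$.

`fit_madc()` maximises the multinomial likelihood of the response counts.
Two variants mirror how sessions are run: with two saliency levels the four
parameters $(d'_v, d'_a, c_v, c_a)$ are fit separately per level (catch
trials are shared); with graded saliencies each modality's $d'$ follows the
three-parameter hyperbolic psychometric
$d_i = d_{\max} x_i^{\,n} / (x_i^{\,n} + s_{50}^{\,n})$
and eight parameters are fit jointly. Fits with an implied visual threshold
($s_{50}$) below 1° or above 45° are flagged invalid. The optimiser uses ten
bounded quasi-Newton restarts with seeded jitter; ties go to the best
likelihood. $d'$ from raw rates uses
$d' = \Phi^{-1}(\text{hit}) - \Phi^{-1}(\text{FA})$ with the $1/(2N)$
convention at rates of exactly 0 or 1 (the source is silent on the clipping
rule; $1/(2N)$ is the field's common choice).

## Side-detection (multinomial logistic) model

For two-sided detection tasks, the log-odds of right and left choices
against no-go are linear in saturated stimulus intensities,
$\log(p_{right}/p_{nogo}) = b_{right} + sL_{right}\,cL^n + sR_{right}\,cR^n$
(and analogously for left), with a shared saturation exponent
$n \in (0, 1]$. `fit_mnlogit()` is a seven-parameter ML fit.

## Catch-trial insertion and session filters

`insert_artificial_catch()` places additional catch events inside long
inter-change intervals, at times drawn from the session's own truncated
exponential ITI law and at least 3 s from real changes, so they do not alter
the animal's temporal expectation. Spontaneous licks inside the response
window make the inserted trial a false alarm; inserted FAs are then thinned
by a density-ratio rule so that their latency distribution matches the hit
reaction-time distribution. `session_filters()` trims a session from the
first run of 20 consecutive no-response trials and excludes sessions whose
maximal-saliency hit rate is below 30%. `silencing_effect()` computes the
relative $d'$ reduction under late silencing per session — including a
session only if early silencing reduced maximal-saliency $d'$ by at least
50% (configurable to 25% or 75%), an internal control for optogenetic
efficacy — and regresses it on the session's median control reaction time.

# Rates, cell types and layers

Spikes are counted in 10-ms bins and convolved with a **causal**
half-Gaussian kernel (default SD 50 ms, truncated at 4 SD, renormalised to
unit mass so rate estimates stay unbiased); causality guarantees that no
future spikes influence the rate at time $t$, which matters for onset
estimation. Alternative SDs are parameters, not code paths: 10 ms for
high-resolution coding analyses, 100 ms for noise correlations (slow
comodulation survives, fast Poisson noise averages out). Z-scoring uses the
pre-stimulus baseline (−1 to −0.2 s), pooling all trials × baseline bins per
neuron (the source does not state whether per-trial means or all bins are
pooled; we pool everything, and neurons with zero baseline variance are
flagged rather than divided by zero). Cell types follow the waveform
peak-to-trough bimodality: narrow < 0.45 ms, broad > 0.55 ms, intermediate
unclassified, capped at 1 ms. The granular layer spans 400–550 µm from the
dura, boundaries inclusive.

# The encoding model

The design matrix covers −0.5 to 2.5 s around each change in 10-ms bins.
Binary events are convolved with **raised-cosine** bases,
$b_j(t) = \tfrac12\big(1+\cos(\pi (t - c_j)/w)\big)$ on $|t-c_j|<w$. With
$w$ equal to the centre spacing adjacent bumps sum exactly to 1 on the span
interior (a partition of unity); we adopt this as the meaning of the basis
"width" since a raised cosine has no standard deviation in the Gaussian
sense. Families: sensory (2 early bases on 0–200 ms + 10 late on 0–2000 ms,
per modality × change level × post-change orientation pair AB/CD = 96
columns), hit (10 stimulus-aligned + 10 reward-aligned = 20; the
stimulus-aligned kernels are shared across modalities by default — the
published predictor total constrains the count to 10, not the sharing — and
a 5 + 5 split per modality is available behind a flag), movement (3 bases
around each lick × 2 sides = 6), pupil (lags 0/−400/−800 ms = 3) and trial
number (1): 126 predictors, each scaled to maximum magnitude 1. The null
model is a single random column.

Fitting uses `glmnet` (Poisson deviance, elastic-net mixing
$\alpha = 0.95$), five cross-validation folds assigned **per trial** so a
trial's bins never straddle folds (the source is silent; per-bin folds would
leak within-trial autocorrelation), and the `lambda.1se` rule. Explained
variance is $EV = 1 - \mathrm{var}(Y-\hat Y)/\mathrm{var}(Y)$, computed
overall, per time bin, or on the concatenated condition-averaged time
courses of the five most frequent trial-type × choice combinations.
Held-out predictions use the cross-validation pre-validated fits; family
subsets zero all other coefficients while keeping the intercept, so the
all-family subset reproduces the full model exactly.

# ROC analysis and coding onsets

Per-bin discriminability between two trial groups is the ROC area, computed
exactly through the Mann–Whitney relation $AUC = U/(n_1 n_2)$ with midranks
for ties, rectified to $[0.5, 1]$. Significance comes from 1000 label
shuffles shared across bins, with
$p = (1 + \#\{\text{shuffled} \ge \text{observed}\})/(1 + n_{shuffle})$ so
$p$ never reaches zero; a bin is significant at $p<0.01$. A neuron is a
*coder* if at least three consecutive 25-ms bins are significant within
0–1000 ms. Orientation coding compares the AB vs CD post-change pairs,
occurrence coding visual vs catch trials, and hit/miss coding visual hits vs
misses.

The population coding fraction is the per-bin fraction of significant
neurons; it is baseline-subtracted and max-normalised only when it rises at
least 0.10 above baseline (a relative rule would trigger on noise around the
~1% false-positive floor). The coding **onset** is the first post-stimulus
bin where the fraction exceeds its baseline mean plus $z$ pooled baseline
SDs ($z = 2$ by default, robustness reported at 1 and 3). Because a
binomial fraction crosses a $2\sigma$ threshold in isolated single bins at
roughly 2% per bin by construction, estimators that run inside resampling
loops (`bootstrap_onset()`, and session-level onsets via
`cohort_onset_summary()`) require two consecutive above-threshold bins by
default — the same consecutive-bin logic as coder classification — while the
plain single-bin rule remains the default of `onset_from_fraction()`.
Session-level onsets apply the AUC analysis to the rate averaged over a
session's neurons (at least ten). The onset-vs-reaction-time relation is
summarised two ways: an ordinary least-squares regression across sessions,
and a slope-1 fit whose offset, `mean(RT − onset)`, measures how long coding
precedes the report; the offset is computed on cohort-level bootstrap
summaries, matching how the corresponding published figure is constructed.

Laminar maps bin neurons into 50-µm depth bins (0–1150 µm, 23 bins) × 25-ms
time bins; a 2-D Gaussian of SD 1.3 bins is applied for display only and the
raw map is always returned.

# Noise correlations and population decoding

Residual rates subtract each condition's trial-mean time course (per
post-change orientation; lick-aligned analyses subtract the lick-aligned
mean). Pairwise Pearson correlations are computed per 10-ms bin across
trials for pairs sampled in at least ten trials, both neurons above 1 Hz.
Pair summaries average Fisher-z-transformed correlations and back-transform
(the source does not state its averaging rule; Fisher-z averaging is the
statistically standard choice for correlations). The decorrelation onset of
a reaction-time tertile is the first bin where its mean correlation falls
below the baseline mean minus 2 baseline SDs. For lick-aligned series the
threshold is taken from the **stimulus-aligned** baseline of the same
tertile (passed via `baseline_stats`): in lick-aligned time the stimulus
transient sweeps through the pre-lick window at an RT-dependent position and
would contaminate a locally estimated baseline.

Orientation decoding groups the post-change orientations into the AB/CD
pairs and uses spike counts in 200-ms windows sliding by 50 ms, dropping
windows that straddle the change (they would mix pre- and post-change
spikes). Sessions require ≥15 neurons and ≥20 trials per class; 10 neurons
are subsampled from larger populations (both thresholds are implemented as
stated in the source, whose 15-to-include / 10-to-subsample combination is
internally tense but harmless). A 200-tree random forest is evaluated by
5×5 stratified cross-validation, and the mean accuracy over 50
label-permuted surrogates is subtracted so chance maps to zero. All
randomness (subsampling, folds, surrogates) is governed by one seed.

# The synthetic-session generator

`simulate_session()` is first-class, tested code, not a fixture. Trial
sequences are block-shuffled per 10 trials (10% catch, 41% visual, 41%
auditory, 8% multimodal) with exponential inter-change intervals of mean
6 s, truncated by rejection to 3–20 s (the rate parameter applies before
truncation). Choices are generated by the same bivariate decision rule the
fitting assumes; reaction times are lognormal, truncated to the 0.1–1.5 s
response window.

Spiking is an inhomogeneous Poisson process on 10-ms bins within −1 to
2.5 s of each change (homogeneous baseline spiking fills the gaps so
session-average-rate and stability filters behave):

$$\lambda_i(t) = g(t)\,\big[\,\beta_i + E_i(t) + L_i(t)\,\big],$$

* $\beta_i$: baseline rates lognormal across neurons (median 5 Hz, log-SD
  0.5 — typical cortical values).
* $E_i(t)$: orientation-tuned early transient, an alpha-shaped bump peaking
  at 60 ms within 0–200 ms, scaled by saliency (0.6 at threshold, 1 at
  maximum) and a laminar gain (largest in the granular/supragranular
  layers). Amplitudes are expressed in units of the neuron's analytic
  baseline rate SD under 50-ms smoothing, so a configured gain of 3 yields
  a ≈3 z trial-averaged response by construction.
* $L_i(t)$: late component on hit trials only, starting at
  $RT + \text{lag}$ with lag −280 ms, rising as a half-Gaussian
  (σ = 100 ms), sustained until the choice, decaying afterwards, strongest
  in supragranular/infragranular layers. Half the neurons participate
  (`late_participation = 0.5`), and each neuron-trial draws an independent
  lognormal amplitude factor (log-SD 0.8) and a small onset jitter
  (SD 40 ms). This heterogeneity is essential realism: a perfectly
  coherent, deterministically timed late component would inject its timing
  variability into every pair's residuals and produce large *positive*
  noise correlations during the late window, the opposite of what recorded
  populations show.
* $g(t)$: a shared multiplicative Ornstein–Uhlenbeck gain (mean 1, time
  constant 1 s) whose SD is solved numerically so that the analytic mean
  pairwise correlation of 100-ms-smoothed counts equals the configured
  baseline target (0.063). The gain deviation is set to zero ("quenched")
  from 200 ms before each first lick, producing the pre-report
  decorrelation.

Reaction-time medians default to 0.44 s (unisensory-trained) and 0.57 s
(multisensory-trained) with log-SD 0.15: with the −280 ms lag these place
the cohort coding onsets near 160 and 290 ms, the regime the analyses are
designed to resolve, and keep within-session RT spread in the realistic
~100 ms interquartile range. Lick bouts run at ~7 Hz for up to 1.5 s after
each response; the pupil trace is a low-pass-filtered copy of the gain
deviations plus noise, z-scored. Photostimulation reduces rates to 5% of
baseline from 0 ms (early) or 200 ms (late) until the choice; behaviourally,
early silencing converts 85% of visual hits to misses, and late silencing
converts a hit to a miss exactly when that trial's late component would have
started at or after 200 ms — operationalising the interpretation that
detection requires the late wave, and making the behavioural effect of late
silencing grow with reaction time.

**What the generator does not emulate:** biophysics (conductances, LFP),
spike sorting artefacts, non-Poisson spiking statistics (refractoriness,
bursting), eye movements, slow representational drift, and any
stimulus-feature structure beyond the four-point orientation/tone sets.
Passing recovery tests therefore demonstrates correctness of the estimators
under the assumed statistical structure, not robustness to every property of
real recordings.

# Numerical choices and degenerate inputs

* Quadrature: 80-node Gauss–Legendre; response-table rows sum to 1 within
  1e-9.
* Optimisers: bounded L-BFGS-B with 10 seeded restarts (5 in the cheaper
  test paths); non-convergent fits are flagged, never silently returned.
* Rates: kernel truncated at 4 SD and renormalised; empty spike trains give
  valid all-zero tensors; baseline-constant neurons are flagged out of
  z-scored outputs.
* Permutation p-values use the +1 convention and so never reach zero.
* Ties in "first significant bin" are resolved to the earliest index.
* Correlations of zero-variance bins are masked (`NA`), not propagated.
* All stochastic steps (generator, folds, shuffles, bootstrap, subsampling,
  surrogates) take explicit seeds; fixed seed implies bit-identical output.

# Problem sizes used by the test suite

The packaged tests validate the chain at deliberately moderate sizes chosen
as the smallest that make the statistical assertions sharp: sessions of
150–350 trials with 8–50 neurons for unit tests; 100 replicates of
600-trial sessions for behavioural recovery; 20 random parameter sets
against a $10^6$-draw Monte-Carlo oracle; two 10-session cohorts of
16-neuron, 250-trial sessions for the onset analysis; and twenty 16-neuron
sessions for the decoding null calibration.

# Known limitations

* The hyperbolic-variant likelihood is evaluated row-wise and is the
  slowest fit; it is exercised at small sizes.
* Lick-aligned noise correlations need externally supplied baseline
  statistics (see above); calling them with a locally estimated baseline is
  statistically valid only when the pre-lick window is stimulus-free.
* The encoding model's explained variance on single 10-ms-bin counts is
  intrinsically small for low-rate neurons; condition-averaged EV is the
  more interpretable summary, as in the source literature.
* `run_pipeline()` orchestrates the standard stages on synthetic sessions;
  it is a reproducibility harness, not a general workflow engine.
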