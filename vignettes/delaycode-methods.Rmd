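---
title: "Models and methods behind delaycode"
author: "delaycode authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(delaycode)
```

# Scope

`delaycode` implements the analysis pipeline of a two-task visual
working-memory paradigm in head-fixed mice. Animals alternate in blocks
between a delayed non-match-to-sample Go/No-go task (**WM**), in which the
reward contingency of a grating depends on the orientation of the previous
grating across a grey-screen delay, and a **Discrimination** task with
identical delay, stimulus and reward statistics in which target identity is
fixed and no memory is required. Because raw recordings for this paradigm
are not publicly available, the package ships a synthetic-data generator that
reproduces the statistical structure the analyses assume; every analysis
stage is exercised end-to-end on generated sessions.

# Task and behavior model

**Trial-type process.** Trials are a delay followed by a stimulus; stimuli
are cues (no-go, 80%), probes (no-go, 10%) or targets (go, 10%), with a cue
mandatory after every probe or target. This makes trial types a three-state
Markov chain whose stationary target frequency is 1/12 while the target
probability *conditional on a cue* is 10%.

**Delays.** Delay durations are 800 ms plus an Exponential(mean 800 ms)
draw; draws beyond 4000 ms are replaced by a uniform draw on
[3600, 4000] ms. The resampling touches $e^{-4} \approx 1.8\%$ of trials and
the resulting mean is $1600 - 1000e^{-4} \approx 1581.7$ ms, i.e. the
nominal 1.6 s. `sample_delay()` implements exactly this process and the test
suite checks both moments against numerical integration of the density.

**Stimulus durations.** In the experiment the stimulus period is a distance
the animal must traverse, so its duration depends on running speed. We do
not model locomotion; durations are lognormal with median 1967 ms and
$\sigma_{\log} = 0.2$, preserving the observed central value and a realistic
spread.

**Responses.** A lick within 1 s of stimulus onset is a response: targets
become hits/misses, cues and probes false alarms (FA) or correct rejections
(CR). The defining behavioral signature of memory decay is a *linear*
increase of WM-task cue FA probability with the preceding delay duration
(default slope 0.119 per second); Discrimination cues and probes are
delay-independent. The functional form is a modeling choice (the analyses
report a fitted linear slope; no generative form is given) and probabilities
are clipped to [0, 1]. Reaction times are Gaussian with a WM-task shift
(163 ms for cues, 70 ms for targets by default). Optogenetic silencing at
delay onset can add a FA-probability boost that expires after a
configurable recovery time, and the cue-FA probability can be coupled to the
per-trial neural code gain (`code_coupling`), which is what links code
collapse to behavioral errors in the outcome-split analyses.

# Neural-population model

`simulate_population()` plants four kinds of structure, at the deconvolved
activity level (all analyses in the pipeline operate on deconvolved traces):

1. **Sequential low-dimensional dynamics.** Gaussian bumps (default 3,
   SD 500 ms) tile the delay; each cell carries one bump with a lognormal
   loading. These dynamics are identical in expectation across tasks: they
   represent timing/reward-expectation processes that working memory does
   not alter.
2. **High-dimensional task and cue codes.** Fixed sparse directions over
   `code_participation` of the cells, orthogonalized against the bump
   subspace *and* the shared-variability modes below, switched on during
   WM-task delays. The cue code's sign follows the preceding mirrored
   stimulus (class B positive). Per-trial lognormal gains (CV
   `code_trial_cv`) have AR(1) correlation `persistence_rho` between the
   early and late delay halves, and a fraction `gain_shared` of gain
   variance is common to both codes (the substrate of the correlated
   task/cue decodability analysis).
3. **Stimulus responses.** A dense transient (exponential kernel, 800 ms)
   plus a sustained stimulus-identity code that lies *inside* a dominant
   shared mode: stimulus identity is low-dimensionally embedded, memory
   codes are not. This is the dissociation probed by the PC sweeps.
4. **Noise.** I.i.d. Gaussian noise per cell and frame (default SD 0.15)
   plus ~110 orthonormal shared-variability modes with unit SD. The shared
   modes are essential: they reproduce the empirical situation in which the
   top ~100 principal components carry the vast majority of population
   variance while the memory code lives in the residual, "uncorrelated"
   modes. The summed activity is rectified at zero (baseline 1.2 keeps
   clipping below ~3% of samples).

The generator returns its ground truth (code directions, bump loadings,
per-trial gains) as an attribute, which the tests use for parameter-recovery
checks.

**Axons and boutons.** `simulate_boutons()` reuses the population model at
the axon level (22.78 Hz), adds axon-specific sparse "private" events (rate
0.4 Hz, exponential amplitudes) — it is these idiosyncratic signals that
make boutons of one axon clusterable in practice — and copies each axon into
$1 + \mathrm{Poisson}(7)$ boutons (mean 8) with independent noise.
Delay-onset silencing multiplies the cue-code amplitude by
$1 - \texttt{silencing\_cue\_attenuation}$ from delay onset until
`silencing_recovery_ms`; bumps and mean activity are untouched, i.e.
silencing of the upstream area is modeled as *modulatory* with respect to
the feedback it disrupts.

# Analysis stages and their conventions

**Filtering and alignment.** Trials with halts or delay licks, trials
following a probe or target (type fully predictable), and delay-end
silencing trials are excluded everywhere; imaging analyses additionally cap
delays at 3.2 s (longer delays are too rare per session). Time is
milliseconds, 0-based, with half-open windows $[t_0, t_1)$; a frame belongs
to an epoch iff its timestamp midpoint lies inside it. At 4.68 Hz a 1.6 s
window therefore holds 7 or 8 frames depending on frame phase. Frames never
straddle the delay/stimulus boundary of a trial.

**Experiments.** Neural activity is compared across tasks only after
identical sensory input. Cue orientations are matched across opposite
±15° rotation blocks (the vertical Discrimination cue rotated -15° matches
the WM cue whose rotated orientation is -15°, and likewise at +15°), giving
up to two experiments per session; sessions with a single usable match are
one experiment spanning the whole session.

**Psychometrics.** d′ is `qnorm(hit rate) - qnorm(FA rate)`; infinities
(no misses, or no false alarms) are treated as missing. Response curves use
100 ms delay bins with Clopper-Pearson 95% intervals and a count-weighted
least-squares slope; reaction-time peaks are the mode bin of a 16.67 ms
(one display frame) histogram, with no smoothing. Silencing effects are
two-sided Fisher exact tests per (area, onset, task, trial type), Bonferroni
corrected across the three trial types within (area, onset, task) — the
correction procedure is unnamed in the source material, and Bonferroni is
the conservative choice; both raw and adjusted p-values are reported.
Performance maps use 100 − FA% − miss%.

**Selection.** Responsiveness is conjunctive: an effect of more than 0.2
activity units (post- minus pre-onset, windows of 800 ms by default — the
window length is our choice) *and* a paired t-test at α = 0.01. Axonal delay
responsiveness slides 1 s windows over the delay against the last second of
the preceding stimulus, Bonferroni-corrected over windows. Latencies are
Gaussian fits (Levenberg–Marquardt) to odd-trial averages, with even trials
reserved for display, so latency sorting is cross-validated. Fits start from
the trace's center of mass; a fit is accepted only if the mean lies in the
window, the width is between half a frame and the window span, and the
amplitude exceeds three residual SDs (flat traces have no latency). Widths
beyond half the window are flagged `wide` (bimodal responses).

**Geometry.** The pooled pseudo-population matrix concatenates per-cell
trial-averaged delay and stimulus responses across experiments; PCA is
mean-centered per cell with timepoints as observations. Trajectories are
display-smoothed with a causal half-normal filter (σ = 100 ms); the
statistics path never smooths or interpolates, and a test asserts the
statistics are bit-identical for σ ∈ {50, 100, 200} ms. The task-distance
null shuffles task labels within experiment (without delay stratification;
stratified shuffling is a possible refinement we judged unnecessary because
delays are task-independent by design) and the per-timepoint two-sided
t-tests use α = 0.05 divided by the realized timepoint count — with 24
timepoints this reproduces the canonical 2.08 × 10⁻³.

**Coding dimensions.** The discrimination vector solves
$(\Sigma + \gamma I)\,w = \mu_a - \mu_b$ with Σ the covariance of the
trials × cells matrix of delay-averaged activity (unbiased, $n-1$
normalization) and γ = 10⁻⁴ stabilizing the inversion. Incorrect and
silenced trials are excluded from training and scored with the
correct-trial models. Predictions use the midpoint of the projected
training-class means (the prediction rule is unstated in the source; the
midpoint rule is the natural one for a 1-D projection). Leave-one-out
decoding removes each trial from the covariance by an exact rank-one
Sherman–Morrison downdate — algebraically identical to refitting, verified
against per-fold refits to 10⁻⁹. Held-out projections are z-scored with
training-fold statistics; auxiliary projections (early/late delay means)
are centered at the fold's projected class-mean midpoint, because a common
projection offset would otherwise masquerade as class signal after
sign inversion. Persistence uses trials with delays ≥ 2 s, z-scores the
early (< 1.6 s) and late (≥ 1.6 s) projections across trials (after
inverting Discrimination-task or cue-A signs) and reports the least-squares
slope and R². The outcome-split analysis replaces the delay average by the
mean of five randomly sampled delay frames (1068 ms of data at 4.68 Hz) so
that delay length does not confound signal-to-noise with FA probability.

**Axons.** Boutons are represented by their loadings on d = 40 temporal
independent components (deflation fixed-point ICA, tanh contrast, PCA
whitening). Components whose fixed-point update falls below the sampling
noise floor carry no detectable non-Gaussian structure and are completed
with an arbitrary orthonormal direction — distances in feature space, which
the clustering uses, are unaffected. Clustering is a Gaussian mixture
(diagonal/spherical covariance families; full covariances are
overparameterized at typical bouton counts) with the number of components
minimizing a small-sample-corrected AIC (AICc; plain AIC where the
correction is undefined because parameters approach the bouton count, and
BIC available as an alternative) — the "adjusted" criterion of the original
pipeline is unnamed, so this is an interpretation and is flagged as such.
Boutons beyond the 0.99 χ² quantile of Mahalanobis distance to their
component are left unassigned; members are averaged into putative axon
traces. Per-unit silencing effects compare the delay-averaged activity
difference (silenced − control) against a null built by resampling control
trials into pseudo-arms, reporting both the percentile p-value and a t-type
p-value against the null's moments. Feedback disruption is quantified as
the control-minus-silenced difference of cue-code projections, separately
for the early and late delay halves, tested across experiments by
signed-rank; mean activity and PC1 serve as net-effect controls (modulatory
silencing should leave both flat). The recovery index is the early-minus-
late effect difference and applies identically to neural and behavioral
effect sizes.

# Design decisions on open points

- *Averaging across mice* (equal weight per mouse vs per trial): both are
  available — `dprime_by_delay_quartile()` returns pooled and per-mouse
  results side by side.
- *Delay-average boundary frame*: a frame straddling stimulus onset is
  excluded from the delay (midpoint rule); this is unverified against the
  original pipeline and flagged here.
- *z-scoring of projections*: per experiment over included trials, with
  training-fold statistics applied to held-out trials (leakage-free).
- *Random-cell sweep*: 50 repeats per cell count by default; repeat counts
  are unstated in the source.
- *Axonal z-scores*: session-wide statistics (not delay-epoch).

# What passing tests do and do not show

The generator's defaults are the paradigm's stated conditions (trial-type
probabilities, delay distribution, 11.9%/s FA slope, 163/70 ms reaction-time
lags, 8% behavioral / 15% axonal silencing fractions, eight boutons per
axon). Free parameters with no printed counterpart (code amplitude 0.35,
participation 0.5, gain CV 0.25, i.i.d. noise 0.15, ~110 shared modes) were
chosen once so that a single simulated experiment lands in the reported
qualitative regime: task/cue decoding near 0.9, most variance in the top
~100 PCs, above-chance decoding after removing them. They are choices, not
claims about the data.

Synthetic data are Gaussian-noise driven, rectified, and stationarity is
exact; real deconvolved calcium traces are sparse, heavy-tailed and
non-stationary (bleaching, state drift). Passing tests therefore validate
the *statistical machinery* — estimator correctness, leakage-free
cross-validation, calibrated nulls, regime-level reproduction of the
dissociations — not the biological conclusions themselves.

Two behaviors of the pipeline on synthetic data deserve explicit mention:

- **Same-sample PC removal is anti-conservative in reverse.** Excluding
  top PCs estimated from the very trials being decoded absorbs
  signal-correlated noise; when a planted code is almost fully captured by
  the removed subspace, the residual is *anti*-correlated with the label
  and held-out accuracy falls below chance (label permutations stay at
  0.50). We report this as the "collapse" of low-dimensionally embedded
  stimulus information; analyses of real data with this design share the
  artifact.
- **Regression-slope persistence is attenuated by projection noise**
  (classical errors-in-variables). Parameter recovery of the AR(1)
  persistence is therefore assessed in a low-measurement-noise regime
  (noise SD 0.01, planted-direction projections); at the default noise the
  attenuation is predictable from the noise-to-gain variance ratio and is
  documented, not hidden.

# Problem sizes and determinism

All simulations are seeded and bit-reproducible. The test suite uses
sessions of 150–5000 trials and populations of 25–300 cells; the silencing
dissociation is checked over 200 simulations per regime, each pooling 12
axonal-imaging experiments (24 axons, 110 trials) and 40 behavioral
experiments (160 trials), mirroring the pooling of behavioral and
imaging experiments that such analyses use for statistical power. Null calibrations use 1000–2000
simulations. `scripts/acceptance.R` regenerates the delay-distribution and
trial-type statistics from scratch (5 × 10⁵ delay draws, 3 × 10⁵ trials)
under a caller-supplied seed.
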