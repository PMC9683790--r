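---
title: "Event-aligned analysis of VIP interneuron imaging sessions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-aligned analysis of VIP interneuron imaging sessions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vipmode` analyses trial-structured two-photon calcium imaging of
VIP-expressing inhibitory interneurons recorded while head-fixed mice
perform an auditory go/no-go discrimination. Each trial ends in one of
four outcomes — Hit (go tone, lick, water reward), False Alarm (no-go
tone, lick, air-puff punishment), Miss, and Correct Rejection — and
reinforcement is delivered 0.5 s after the triggering lick. The package
implements the full analysis chain for such sessions and, because real
recordings carry no ground truth, ships a synthetic session generator
whose planted structure every stage is validated against.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
establish about real data.

## The synthetic session generator

`session_config()` + `generate_session()` draw a complete session:
trial outcomes (Bernoulli go/no-go and lick draws), log-normal reaction
times truncated to [0.1, 1.5] s, lick bouts, reinforcement onsets at
first lick + 0.5 s, behaviour traces, and per-neuron fluorescence.

Each neuron's raw trace is

    F(t) = F0 * (1 + s(t) + e(t)),    e(t) ~ N(0, noise_sd)

where the dF/F signal `s(t)` places the neuron's temporal archetype
kernel at each reinforcement it responds to, scaled by its gain and by
the trial's arousal multiplier `1 + arousal_gain * dP/P`. Kernels are
evaluated at the exact fractional-sample offset of the event and
normalised by their continuous-time peak, so trial averaging does not
blur the planted shape.

**Response archetypes.** The five temporal profiles — fast, delayed,
sustained, biphasic, slow — are difference-of-exponential kernels
(`archetype_kernel()`). Only their qualitative shapes are established
for real VIP neurons; the time constants here (rise/decay in seconds:
fast 0.1/0.5; delayed = fast with 0.5 s onset latency; sustained 0.1/3;
biphasic = fast plus a 0.6-weight lobe peaking near 2 s; slow 1/5) are
this package's parametric choice: smooth, causal, GCaMP6f-like, and
mutually discriminable. Recovery tests are therefore calibrated against
these kernels, not against any published cluster profile. The default
archetype mix (0.18, 0.145, 0.29, 0.20, 0.185) follows the relative
cluster sizes reported for reward-activated VIP neurons.

**Responder structure.** Each neuron is assigned a responder category
(`both` 0.73, `reward_only` 0.10, `punishment_only` 0.12, `none` 0.05 by
default), matching the reported fractions of neurons driven by both or
either reinforcer. Reward and punishment gains share a per-neuron
log-normal factor (sdlog 0.40) with reinforcer-private factors (sdlog
0.231); this places the population Pearson correlation between reward
and punishment amplitudes at 0.73, the reported value, via
`corr = (exp(s_g^2) - 1) / (exp(s_g^2 + s_e^2) - 1)`.

**Arousal coupling.** Pupil diameter is a slow mean-reverting (AR(1)/OU)
baseline plus an event-evoked dilation kernel peaking about 1 s after
reinforcement, with per-trial log-normal dilation amplitudes. The
defaults — median dilation 0.08 dP/P with sdlog 1, arousal gain 4, and
trace noise 0.15 dF/F — were set so that three published statistics hold
simultaneously at the defaults: the high/low pupil-split group dilations
land near 14% vs 3% dP/P, the split response ratio lands near 28% vs 18%
dF/F, and the median per-cell pupil–activity correlation lands near
0.31. These are study conditions, fixed once; tests run at them.

**Other planted structure.** Soma diameters come from a two-component
Gaussian mixture (means 8 and 11 um, sd 0.8, equal weights), emulating
the reported bimodality. Locomotion is sparse smooth bouts, a fraction
of them (`run_coupling` = 0.3) time-locked to reinforcement. Blinks
insert `NA` runs into the pupil trace to exercise gap interpolation.
Tile stacks (`generate_tile_stack()`) render a smooth random scene with
soma-like blobs through a bilinearly interpolated window, so subpixel
shifts are exact by construction.

**What the generator does not emulate.** Spike-to-calcium biophysics
beyond the double-exponential kernel, photon shot noise, neuropil
contamination, slow drift/bleaching, eye movements, and genuine 3-D
scanning physics. Passing recovery tests therefore demonstrate that the
analysis code is correct under its stated assumptions — not that those
assumptions exhaust real recordings.

## Trace preprocessing

`compute_dff()` uses the task convention: per-trial baseline F0 = mean
raw fluorescence over [-2, 0] s before each tone, applied piecewise
until the next trial; a global percentile baseline (default 20th) is
available for continuous traces but has no task-data validation.
Baselines must be positive; violations name the offending neuron.

`align_trials()` cuts a neurons x time x trials array with linear
interpolation onto a regular grid containing t = 0 exactly. Modes:
`cue` (tone onset), `reinforcement` (Hit/FA only), and
`expected_reinforcement`, which aligns Miss/CR at
`tone + mean reaction time (over the session's Hit and FA trials) +
reinforcement delay` so unreinforced trials can be compared at the time
reinforcement would have arrived. Trials whose window leaves the
recording are dropped with a warning rather than padded — padding would
fabricate samples.

`estimate_kinetics()` reports the post-event peak time and a
least-squares exponential decay constant (log-linear start refined by
Levenberg-Marquardt); a non-decaying post-peak segment returns `Inf`
rather than a spurious constant.

## Responsiveness and population statistics

`classify_response()` subtracts each trial's baseline mean, takes the
per-trial response-window means (0-2 s after the event vs -2-0 s
baseline), and applies two one-tailed one-sample t-tests at 0.05 per
tail: activated if the positive tail is significant, suppressed if the
negative one is. The combined null rate is therefore ~10%, which a
2,000-neuron null simulation confirms to within 0.02. A Lilliefors
normality test on the same per-trial means is recorded as metadata but
never gates the t-test, mirroring the original analysis logic (most
cells test normal; the classifier is applied regardless). The t-test
operates on per-trial means rather than all time samples — the source
analysis leaves this ambiguous; per-trial means keep the test's
independence assumptions defensible. No multiple-testing correction is
applied by default (raw p < 0.05 per neuron), matching the analysis
being reproduced.

`trial_activity()` marks a neuron active on a trial when the mean of
the 250 ms around the post-event peak exceeds the baseline mean by
strictly more than two baseline SDs. The SD is that trial's own
baseline-sample SD — the only SD computable for a single trial. A
zero-SD baseline with any positive excess counts as active; a fully
flat trial does not. Synchronicity (active fraction per trial) and
reliability (active fraction per neuron) obey the exact double-counting
identity `sum(sync * n_neurons) = sum(rel * n_trials)`, asserted on
random matrices.

`cv_partition()` separates cell-to-cell variability (CV over cells
within a session, averaged over sessions) from inter-individual
variability (CV over session means), both with sample (n-1) SDs.

## Archetype clustering

Profiles are the trial-averaged Hit responses of reward-activated
cells: z-scored by the mean/SD of the first second of the aligned
window, then divided by the maximum absolute amplitude over 0-4 s after
reward. Cells with zero first-second SD are excluded, as are outliers
whose profile norm exceeds 5x the median norm — a reproducible surrogate
for the original analysis's unexplained exclusion of cells that
"disproportionately" hurt reconstruction. PCA retains the smallest
component count reaching 90% cumulative variance; k-means (k = 5) runs
five k-means++ replicates and keeps the lowest within-cluster sum of
squares. At generator defaults the planted archetypes are recovered
with adjusted Rand index ~1.0 (the acceptance suite requires >= 0.9
over a 10-seed ensemble of 200-neuron sessions).

Feature projections use unit-normalised cluster mean profiles (the
source is silent on normalisation; unit norm makes scores comparable
across clusters). Area contrasts use two-sided Mann-Whitney tests; the
depth-homogeneity test is a one-way ANOVA — the original statistic is
unnamed, and this choice is flagged as an assumption.

## Trial tensor and non-negative CP decomposition

`build_tensor()` extracts, per cell and trial, the reaction-time
segment (tone to reinforcement for Hit/FA; tone to tone + session-mean
reaction time for Miss/CR, which have no lick) and linearly warps it to
30 points spanning 1.5 s. Cells are offset to non-negative values and
normalised by the mean over Hit trials of per-trial maxima; the first
10 trials of each outcome are kept (K = 40), sessions with fewer are
excluded rather than padded.

`nncp_decompose()` is a hierarchical alternating least squares (HALS)
non-negative CP solver written for this package: per mode and component,
`a_j <- max(0, a_j + (W_j - A G_j) / G_jj)` with `W` the unfolding times
the Khatri-Rao product and `G` the Hadamard product of Gramians.
Iteration caps at 500 sweeps with a 1e-8 relative-error tolerance; the
best of 10 random (uniform) initialisations is kept, all seeded. A zero
tensor is rejected as degenerate. Planted rank-1 structure is recovered
to < 1% error with factor cosines >= 0.99, the error is non-increasing
in rank over 1-5, and a planted reinforcement motif yields a trial
factor separating Hit/FA from Miss/CR at p < 0.001 (Mann-Whitney) in
>= 95% of seeds.

## Arousal and locomotion modulation

`normalize_pupil()` interpolates blink gaps up to 0.5 s linearly
(boundary gaps extend the nearest value; longer gaps flag overlapping
trials as dropped — the original workflow interpolated blinks manually,
which is not reproducible), smooths with a 100 ms Gaussian (no value is
published; 100 ms removes eye-movement artefacts without distorting
second-scale dilations), and computes per-trial baselines over [-2, 0] s
before tone, giving dP/P = (P - P0)/P0.

`auc_split()` integrates dP/P trapezoidally over 0-3 s after
reinforcement and median-splits trials within each outcome; ties at the
median go to "low", a deterministic rule that is conservative for the
high-arousal effect. `speed_change()` does the analogous split on the
Gauss-filtered absolute running speed (event window minus pre-tone
baseline; tone window for unreinforced trials).
`compare_split_responses()` compares per-neuron group means with a
paired t-test and reports the initial (0-1 s) and late (2-3 s) phases.

`no_arousal_subset()` keeps reinforced trials whose post-reinforcement
(0-1 s) pupil and speed changes stay within two SDs of their own
baseline fluctuation, then tests whether the population response on
those trials is still positive. The window is taken as [0, 1] s after
reinforcement; the source prints the interval with reversed bounds,
which is treated as a typo. Because the pupil baseline is autocorrelated,
a modest fraction of trials is excluded even with no planted dilation;
tests account for this.

## Behavioural-kernel lasso

`build_design()` assembles five standardized predictors at the imaging
rate: a 0.5-s boxcar per auditory cue; a water regressor whose kernel
rises as a Gaussian from delivery to the session's lick-rate peak and
then decays linearly to zero at the time the lick plateau has dropped
5% from its peak (sessions without licks fall back to a fixed 2-s
kernel, logged); an air-puff kernel peaking 0.2 s after onset with
sigma = 64 ms so the onset value stays below 1% of peak; the smoothed
pupil trace; and the absolute running speed, block-mean downsampled
when behaviour is sampled faster than imaging. Constant columns are
excluded. An optional uniform-random control column verifies that the
fitted model ignores uninformative regressors.

`fit_lasso()` selects the penalty on a 50-point log grid spanning
`1e-4` to `1e1` times the all-zero penalty, by 5-fold cross-validation
over contiguous time blocks — shuffled folds would leak autocorrelated
samples between train and test and inflate the variance explained.
Variance explained is the mean held-out R-squared at the selected
penalty. The modelled response is the population-mean dF/F;
`simulate_population_signal()` plants weights ordered
pupil > water > air puff > speed > cue (the reported predictor
ordering), which the fit recovers in >= 90% of seeds.

## Visual tuning

Direction responses are baseline-subtracted means over repeats of eight
grating directions at 45-degree spacing, clipped at zero so the indices
stay in [0, 1]. `OSI = (R_pref - R_ortho)/(R_pref + R_ortho)` with
R_ortho the mean of the two orthogonal directions (the source's
singular "orthogonal orientation" is symmetrised), and
`DSI = (R_pref - R_opp)/(R_pref + R_opp)`. The response window is the
moving-grating period; the source does not state which sub-period
defined amplitudes. The tuning simulator uses
`R(theta) = peak * (1 - m (1 - cos(theta - theta_pref)) / 2)`, for
which DSI = m/(2 - m) and OSI = m/(4 - m) analytically — asserted to 2%
on noiseless input.

## Tile registration

`register_tile()` estimates a translation in two stages: the integer
shift from the peak of the frequency-domain cross-correlation of
Hann-windowed, mean-subtracted images, locally verified against the
overlap correlation of the 3x3 integer neighbourhood (the windowed
circular peak can be off by one pixel at larger shifts); then subpixel
refinement by an iterative gradient-based (Gauss-Newton) translation
solve on the aligned overlap. A quadratic fit of the correlation peak —
the textbook refinement — is biased by ~0.2 px on smooth fluorescence
scenes, which is why the gradient solve is used; it reaches ~0.05 px at
SNR 5. When integer alignment already matches the template to machine
precision the integer shift is returned unrefined, so noiseless integer
shifts are recovered exactly. The matching error is one minus the
aligned-overlap correlation. `select_templates()` averages the
best-correlating 20% of frames per tile (chosen per tile; the source is
ambiguous between per-tile and across-tile selection), and
`consensus_shift()` takes the componentwise median over the lowest-error
20% of tiles, never fewer than three — unchanged under 40% corrupted
tiles. Median filtering and contrast-limited adaptive histogram
equalization (8x8 tiles, clip limit 2) are available as preprocessing.

## Morphometry

`fwhm()` subtracts a baseline (mean of the outer 10% of samples, 5% per
end), finds the peak, and interpolates both half-maximum crossings
linearly; it is invariant to intensity offset and positive scaling and
matches the Gaussian closed form 2.3548 sigma to 1%.
`diameter_bimodality()` fits one- and two-component Gaussians to the
0.5-um-binned diameter histogram by least squares on
Anscombe-transformed counts, `sqrt(y + 3/8)`, whose variance is
approximately constant under Poisson counting noise — on raw counts the
extra-sum-of-squares F-test (3 vs 6 parameters) is anti-conservative.
Fits start from a 2-means split with a quantile fallback; a
two-component fit whose minor component carries < 1% of the mass is
reported unimodal.

## Scan-performance arithmetic

Closed forms for comparing scanning strategies: point-by-point volume
rate `1/(nx ny nz dwell)`; resonant volume rate
`1/(n_lines n_planes / line_rate + n_planes settle)`; and the
ROI-restriction gain `SNR_gain^2 * v_gain = V_total / sum(V_i)` (areas
in 2-D). The resonant line count uses the slow-axis pixel count (507),
which reconciles the printed 0.16 Hz volume rate; the published dwell
formula divides by the fast-axis count instead, an inconsistency noted
rather than resolved.

## Reproducibility and problem sizes

Every stochastic routine takes a seed and restores the caller's RNG
state; `run_pipeline()` propagates one seed everywhere and reproduces
its summary JSON byte-for-byte. The validation suites run sessions of
60-250 neurons and 64-160 trials, tensors around 25 x 30 x 40, and
2,000 null neurons for classifier calibration — sizes at which every
recovery statistic is stable while the whole suite stays interactive.
`scripts/acceptance.R` re-runs the main pipeline on a 200-neuron,
128-trial session plus the closed-form scan arithmetic and writes all
headline quantities as JSON.

## Known limitations

* The archetype kernels and their recovery thresholds are internally
  calibrated; cluster counts and reconstruction errors from real
  recordings will differ.
* The percentile dF/F baseline for continuous traces is provided but
  unvalidated against task data.
* The depth-homogeneity ANOVA and the per-tile template selection are
  assumptions where the source is ambiguous.
* Registration assumes pure translation; rotation and non-rigid motion
  are out of scope.
* The lasso models the population-mean signal, not per-neuron encoding.
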