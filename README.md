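# vipmode

Event-aligned analysis of cortex-wide VIP interneuron calcium imaging.

VIP-expressing interneurons disinhibit cortical pyramidal cells and are
recruited by behavioural reinforcers — water reward and air-puff
punishment — across the dorsal cortex while mice perform an auditory
go/no-go task. Analysing such recordings means answering, per neuron
and per trial outcome (Hit, False Alarm, Miss, Correct Rejection):
did the cell respond, how reliably, with what temporal profile, how
strongly was the response modulated by arousal and locomotion, and how
does it relate to the cell's sensory tuning and morphology?

`vipmode` implements that full analysis chain for trial-structured
two-photon (and photometry-style population) calcium data, plus a
ground-truth synthetic session generator used to validate every stage:

* **Synthetic sessions** — go/no-go trial structure with reaction times
  and a 0.5 s reinforcement delay, five GCaMP6f-like temporal response
  archetypes, arousal-coupled response gain, pupil/locomotion/lick
  traces, bimodal soma diameters, translating tile stacks
  (`generate_session()`, `generate_behavior()`, `generate_tile_stack()`).
* **Preprocessing** — per-trial dF/F = (F − F0)/F0, event alignment
  (cue / reinforcement / expected reinforcement for unreinforced
  trials), Gaussian smoothing, peak-time and decay-constant estimation
  (`compute_dff()`, `align_trials()`, `estimate_kinetics()`).
* **Responsiveness** — two one-tailed one-sample t-tests (with a
  Lilliefors normality check recorded as metadata), the 2-SD trial
  activity criterion, synchronicity / reliability / stability,
  responder category tables, amplitude correlations and CV partitioning
  (`classify_all()`, `trial_activity()`, `synchronicity()`, ...).
* **Temporal archetype clustering** — profile normalisation, PCA to 90%
  variance, k-means (k = 5, five k-means++ replicates), feature
  projections, area and depth contrasts, cue-response linear models.
* **Tensor component analysis** — reaction-time warping to 30 samples,
  non-negative trial tensors, a hand-rolled HALS non-negative CP solver
  with multi-start initialisation, and trial-factor separation of
  reinforced vs unreinforced trials (`build_tensor()`,
  `nncp_decompose()`).
* **Arousal / locomotion** — pupil dP/P with blink interpolation,
  median splits by pupil-dilation AUC or speed change, split response
  comparisons, per-cell behaviour correlations, and the
  no-arousal-change trial subset (`auc_split()`, `speed_change()`, ...).
* **Behavioural-kernel lasso** — cue boxcar, lick-rate-shaped water
  kernel, air-puff kernel, pupil and speed regressors; 5-fold
  contiguous-block cross-validated lasso via glmnet (`build_design()`,
  `fit_lasso()`).
* **Visual tuning** — OSI = (R_pref − R_ortho)/(R_pref + R_ortho),
  DSI = (R_pref − R_opp)/(R_pref + R_opp) over eight grating directions.
* **Motion correction** — FFT cross-correlation tile registration with
  gradient-based subpixel refinement, best-20% template selection, and
  robust low-error-median consensus shifts (`register_tile()`,
  `consensus_shift()`).
* **Morphometry** — soma FWHM from line profiles and Gaussian-mixture
  bimodality testing (`fwhm()`, `diameter_bimodality()`).
* **Scan arithmetic** — closed-form measurement-rate and SNR-gain
  comparisons between point, resonant, and ROI-restricted (chessboard)
  scanning (`point_scan_rate()`, `roi_gain()`, ...).

`run_pipeline()` ties the stages into one seeded, reproducible run with
CSV/JSON outputs. See the methods vignette
(`vignettes/vipmode-methods.Rmd`) for the models, parameter choices and
their rationale.

## Worked example

```r
library(vipmode)

cfg <- session_config(n_neurons = 120, n_trials = 128, seed = 1)
ses <- generate_session(cfg)
ses
#> <vip_session> 120 neurons, 128 trials, 21.5 min @ 20 Hz
#>
#>   CR   FA  Hit Miss
#>   38   22   52   16

al  <- align_trials(ses, mode = "expected_reinforcement", window = c(-2, 4))
cls <- classify_all(al)
round(100 * category_table(cls)$fractions, 1)
#>            both     reward_only punishment_only            none       all_types
#>            80.0             9.2             9.2             1.7             1.7

act <- trial_activity(al)
tt  <- attr(act, "trial_types")
c(synchronicity_hit = mean(synchronicity(act)[tt == "Hit"]),
  reliability_hit   = mean(reliability(act, "Hit")))
#> synchronicity_hit   reliability_hit
#>              0.71              0.71
```

80% of the simulated neurons are classified as responding to both
reward and punishment (this session planted 73% dual responders plus a
~10% false-positive allowance from the two one-tailed tests), and on an
average Hit trial 71% of neurons are simultaneously active — the
population-wide recruitment signature the analysis is designed to
quantify. The same objects feed the clustering
(`preprocess_profiles()` → `pca_reduce()` → `kmeans_cluster()`), tensor
(`build_tensor()` → `nncp_decompose()`) and arousal
(`normalize_pupil()` → `auc_split()` → `compare_split_responses()`)
stages; `run_pipeline(list(seed = 1))` runs them all.

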