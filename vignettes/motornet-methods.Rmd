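---
title: "Motor-network coupling biomarkers: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-network coupling biomarkers: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a first hemiparetic stroke, upper-limb rehabilitation helps some
patients far more than others. A clinically useful biomarker would
stratify patients *before* therapy into those likely to reach a
clinically significant improvement ("favorable") and those who are not
("poor"). motornet implements a complete pipeline for one family of
such biomarkers: directed coupling ("effective connectivity")
between five motor cortices — the supplementary motor area (SMA) and
the ipsi- and contralesional primary motor (iM1, cM1) and premotor
(iPM, cPM) cortices — estimated from movement-task EEG, including both
within-frequency (linear) and cross-frequency (nonlinear) interactions.

Outcome is defined on three clinical scales: a favorable outcome is a
post-rehabilitation improvement reaching 10% of the maximum score on
any of the Fugl–Meyer Assessment (threshold 6.6 points of 66), the Wolf
Motor Function Test (7.5 points), or the TEMPA (16.2 points; the TEMPA
is negative-scored, so improvement is still `post - pre`). Comparisons
use `>=` ("reaching" the level). `label_outcome()` applies the rule;
`label_table()` reports rows whose recorded label contradicts it
without overwriting them — in the packaged table two training patients
(31 and 36) have WMFT improvements of 8 and 9 points yet are recorded
as poor, and downstream analyses follow the recorded labels.

## The induced-response coupling model

The observation of interest is the *induced response*: trial-averaged,
baseline-corrected time-frequency power at each source, expressed as
percent change from the pre-cue baseline. The model treats the vector
`g(t)` of induced power over sources × frequency bands as a linear
dynamical system driven by the cue:

    dg/dt = exp(logtau) * (A g + C u(t))

- `A` holds directed coupling between source–band pairs. Block
  `(i <- j)` maps source *j*'s band power onto the rate of change of
  source *i*'s band power; its diagonal is within-frequency (linear)
  coupling, its off-diagonal entries are cross-frequency (nonlinear)
  coupling. Within-source blocks ("intrinsic") carry the self-decay
  rates on their diagonal.
- `C` is a per-source, per-band input weight; `u(t)` is a Gaussian
  bump (sd 50 ms) at the auditory cue. The data do not say where the
  cue enters, so all five sources receive input by default.
- `exp(logtau)` is a global rate scale with a log-normal prior.

Coupling is parameterized at *band* resolution (theta 4–8, alpha 8–15,
beta 15–30, gamma 30–48 Hz); `full_state_matrix()` expands a band-level
matrix to any frequency grid by spreading each entry uniformly over the
source band's bins, so band-space and grid-space dynamics agree for
band-constant states. Integration is fixed-step RK4 (5 ms in the
forward simulator, 10 ms inside inversion; both configurable), and a
state matrix whose largest eigenvalue real part exceeds the stability
bound is rejected with a diverging-trajectory error rather than
integrated.

### Model space

Two hypothesis axes generate the comparison space: *where*
cross-frequency coupling is allowed (everywhere, intrinsic connections
only, extrinsic connections only) and whether the edge set is the full
9 reciprocal pairs (18 directed connections) or a reduced, more
lateralized 8-pair variant without the iPM–cM1 diagonal pair. That
yields DCM1–DCM6 plus an all-linear model with DCM1's edges and no
cross-frequency terms. The published wiring of the reduced variants is
not recoverable from the source material, so the space is a documented
convention and `model_spec()` accepts any architecture over the 9
canonical pairs.

## Preprocessing

`preprocess_epochs()` chains the standard steps with study defaults:
zero-phase 4th-order Butterworth band-pass 4–48 Hz (the band is stated;
the realization is our choice), rejection of trials exceeding 500 µV on
any channel (strict `>`), mid-sagittal flipping for right-hemisphere
lesions so the ipsilesional hemisphere is always left, Moore–Penrose
pseudoinverse projection through the lead field, a complex Morlet
transform with 7 cycles, and trial-averaged baseline correction over
−850 to −800 ms with cropping to −500 to 800 ms. Baseline correction is
percent change by default — the source material says only "baseline
corrected", and percent change makes coupling parameters independent of
absolute amplitude scale — with subtraction available
(`mode = "subtract"`). Failed-movement trials are carried as a boolean
mask in the epoch container, not detected algorithmically.

## Inversion and model selection

`invert_dcm()` is a variational-Laplace scheme: Gauss–Newton ascent
with Levenberg-style damping on the free energy `F = accuracy −
complexity` under Gaussian priors and likelihood, with analytic
parameter sensitivities propagated through the integrator in compiled
code. Observation noise is one variance per source, profile-updated
each iteration. Accepted steps never decrease F. Convergence is
declared after three successive iterations with |ΔF| below an absolute
tolerance (0.05 nats); an absolute rule is used because F scales with
the number of data points, so a relative rule either stalls early on
large datasets or never fires on small ones. Priors are zero-mean
shrinkage: sd 0.5 on within-band extrinsic couplings, 0.25 (variance
1/16) on cross-frequency entries, intrinsic decay centered at −2 s⁻¹,
diffuse input weights, and a tight prior on `logtau`.

The default reduced space for fitting is the fixed four-band basis
(`project_to_bands()`): data are averaged into the four canonical bands
and the model fitted with one state per source–band. An SVD mode basis
(`reduce_to_modes()`) is provided as an alternative; the band basis was
chosen as the default because recovered `A` entries are then directly
interpretable as band couplings and parameter-recovery correlations
against generating values are well defined.

Group-level selection: `ffx_compare()` sums free energies over subjects
and softmaxes; `rfx_compare()` implements the variational Dirichlet
scheme over model frequencies (uniform prior `alpha0 = 1`), with
exceedance probabilities estimated from seeded Dirichlet sampling
(default 1e6 draws) and validated in tests against exact Beta
quadrature on two-model problems.

## Features and classification

`extract_connection_features()` turns each fitted edge into 8
attributes: per band, the mean of positive entries (excitatory) and the
mean of negative entries (inhibitory), with empty sign classes defined
as 0 so vectors keep fixed length (144 attributes for 18 connections).
Cross-frequency entries are assigned to the band of the *target*
frequency by default — the alternative source-band assignment is a
switch — because a coupling's physiological effect is expressed at its
target. `extract_source_features()` does the same on the spectrogram
itself (40 attributes).

Classification is logistic regression fitted by IRLS on standardized
features with a ridge penalty (default strength 1 on standardized
features; with 37 subjects and 144 predictors an unpenalized fit
separates perfectly, and the original handling of this
underdetermination is unknown — separation without a penalty is
detected and a ridge fallback applied with a flag).
`crossval_accuracy()` is stratified 5-fold cross-validation repeated
100 times by default, standardizing inside each training fold;
`band_combination_search()` scores all 15 non-empty band subsets;
`backward_eliminate()` removes the largest Wald p-value feature until
all remaining are significant at alpha = 0.05 (numerically tied
p-values drop the name latest in sort order, so the earliest name
survives degenerate ties). `evaluate()` reports the confusion matrix
with favorable as positive; undefined ratios are `NA`, never 0, and
displayed percentages round half away from zero to one decimal.

## The synthetic-data generator

No public recordings exist for this task, so `generate_cohort()` and
`simulate_eeg_trials()` emulate the study conditions with known ground
truth: 32-channel 10–20 montage, 2000 Hz, 80 trials, −1500 to 2000 ms
epochs (tests and demos reduce sampling and trial counts; the semantics
never change). Sources are sums of band-center sinusoids whose
amplitude envelopes follow the power model (amplitude = sqrt of
absolute power, baseline 1) — one of many time series consistent with a
target spectrogram, chosen because it is invertible in tests. The lead
field is geometric by default: Gaussian falloff of idealized,
mirror-symmetric 10–20 electrode positions around the MNI source
coordinates, unit-norm columns, optional seeded jitter; a real gain
matrix can be supplied. Input weights default to a scale (sd 150
percent-power units) that produces induced responses of tens of percent
change, the magnitude of real movement-related desynchronization.

The favorable/poor contrast is injected only into the three designated
beta couplings — SMA→cPM (more inhibitory), SMA→cM1 (less inhibitory),
cM1→SMA (more facilitatory) — on top of fixed signed baselines, with
between-subject jitter (sd 0.15) on all nonzero couplings; the group
shift defaults to 0.5. Between-subject variability of coupling is not
characterized in the source material, so it is an explicit
configuration parameter rather than an asserted value. Generated
clinical rows are drawn so that the 10%-rule reproduces each subject's
label exactly (score ceilings are respected when drawing pre scores).

What the generator does *not* emulate: realistic head volume conduction
(no BEM/FEM), ocular or muscle artifacts beyond amplitude outliers,
non-stationary coupling, and the 1/f background spectrum. Passing the
synthetic studies therefore shows the *machinery* is correct and the
design identifiable under its own assumptions, not that real EEG will
behave as well.

## The synthetic validation studies

Three packaged studies (`recovery_study()`, `identification_study()`,
`classifier_study()`) run at documented reduced scales — band-space
grid, observations every 25 ms over −500 to 800 ms, 4 subjects per
dataset or run — chosen so each study completes in minutes on one CPU.

- *Recovery*: data from the full nonlinear architecture at noise sd =
  10% of signal RMS; the correlation between generating and
  posterior-mean nonzero couplings is about 0.85.
- *Identification*: the intrinsic-nonlinear architecture vs the
  all-linear model, 20 runs of 4 subjects at 5% noise, decided by the
  random-effects exceedance probability. Priors are matched to the
  generating distributions (a well-specified setting). The noise level
  matters here for a structural reason: under a single impulsive cue
  input, a per-band linear model with free input weights can absorb
  most cross-frequency structure in the *trajectories*, so the
  evidence discriminates largely through the complexity term and needs
  reasonable SNR. This is a genuine identifiability property of the
  model class, not an implementation artifact.
- *Classifier sanity*: cohorts of 19 + 18 with the beta-only group
  effect. Beta-containing band combinations outrank beta-free ones;
  backward elimination after restriction to the best band combination
  retains at least one injected connection in essentially every seeded
  cohort. Because the three injected couplings shift in lockstep they
  are collinear by construction, and elimination — by design — keeps
  one representative of a collinear group rather than all three; the
  per-connection retention frequencies (~0.5–0.8) are reported
  alongside the any-connection rate. With zero injected effect,
  cross-validated accuracy stays inside the binomial 95% band around
  chance.

## Numerical choices and degenerate inputs

- Band bins are half-open `[low, high)`, upper edge of gamma inclusive,
  so every bin belongs to exactly one band.
- Zero baseline power raises a division-guard error rather than
  producing infinities; subtraction mode is the escape hatch.
- Rank-deficient lead fields give a warning and the minimum-norm
  solution; fewer channels than sources is an error.
- Unstable state matrices error in simulation; inside inversion a
  candidate step that produces non-finite trajectories is rejected and
  damping increased.
- All randomness flows through explicit seeds (simulation config,
  cross-validation, Dirichlet sampling); reruns of the pipeline hash
  identically in the run manifest.

## Known limitations

- The exact wiring of the reduced model variants and the original
  priors, mode counts, and regularization are not recoverable; all are
  configurable and the defaults are documented above.
- Real-data results (group exceedance probabilities, published
  classification accuracies) require the original patient EEG, which is
  unavailable; the synthetic studies substitute parameter-recovery and
  identification checks.
- The forward model is linear in power; genuinely nonlinear phase
  interactions (for example phase-amplitude coupling) are represented
  only through their signature in band-power dynamics.
- Epoch containers serialize to RDS; no EDF/HDF5 readers are bundled.
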