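---
title: "Predicting postoperative delirium from intraoperative EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postoperative delirium from intraoperative EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`podeeg` estimates the risk that an older surgical patient will develop
postoperative delirium (POD), using only data available in the operating
room: the 4-channel frontal EEG (Fp1, Fp2, F7, F8) recorded by
depth-of-anesthesia monitors, and six clinical covariates (age, ASA score,
benzodiazepine premedication, operation length, induction agent,
maintenance agent). This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and — because
clinical EEG of this kind cannot be shared — what the synthetic cohort
generator does and does not emulate.

## 1. Preprocessing

The cleaning pipeline runs in a fixed order.

1. **Amplitude artifact mask.** Amplitudes scale differently across
   subjects and montages, so the threshold is per patient: a sample is
   flagged when any channel exceeds the empirical quantile
   (`amplitudeQuantile`, default 0.99) of the *pooled* absolute amplitudes
   of all four channels. The pooled (rather than per-channel) quantile
   gives one patient-level threshold. The mask is computed on the raw
   signal, before re-referencing and filtering. Flagged samples are
   dilated to their enclosing 0.1 s neighborhood (`artifactDilate`)
   because spikes carry ringing.
2. **Common average reference**: each sample's across-channel mean is
   subtracted.
3. **Band-pass 0.3–50 Hz** (`bandLow`, `bandHigh`): the squared magnitude
   response of an order-5 Butterworth band-pass applied spectrally, which
   is exactly the zero-phase (forward–backward) response. It attenuates
   0.05 Hz drift and 60 Hz interference by more than 20 dB in power. Any
   filter meeting that attenuation contract would serve; the spectral
   application was chosen because it is phase-exact and fast on
   half-hour recordings.
4. **Segmentation.** Maximal artifact-free runs are shrunk by
   `edgePad` (default 1 s) at every boundary — each boundary abuts either
   an artifact or a recording edge, both of which carry filter edge
   effects — and runs shorter than `minSegmentLen` (1 s) are dropped, as
   too short for stable spectral or covariance estimates. Segments are
   half-open `[start, end)` intervals in seconds from recording start.
5. **Z-scoring**: per channel, mean 0 / SD 1 over the concatenation of all
   clean segments, one constant pair per patient. All later thresholds are
   therefore in z-units.

A patient enters the analysis only with at least `minTotalMinutes`
(default 20, boundary inclusive) of clean EEG.

## 2. Burst suppression

A sample counts as suppressed when the channel-averaged RMS envelope
(sliding `envelopeWin` = 0.25 s window) stays below `supprThreshold`
(default 0.2 z-units — an absolute microvolt threshold would be
meaningless after z-scoring) for at least `minSupprDur` = 0.5 s, a
conventional minimum suppression duration. The binary indicator smoothed
by the envelope window is the suppression *timeline* (values in [0, 1],
suppressed where > 0.5).

One numerical subtlety: the envelope is computed on a 3–30 Hz
band-limited copy of the segments (`envBand`). The 0.3 Hz high-pass edge
of the preprocessing filter has ~1 s of memory, so high-amplitude activity
smears across suppression boundaries and would blur onsets and offsets by
up to a second; above 3 Hz the filter memory is tens of milliseconds and
episode edges localize to about 0.1 s.

Scalars: **BSR** = suppressed time / total clean time (the recording
duration reduced by removed artifacts), and **LSP** = duration of the
longest contiguous suppressed run. Runs never bridge segment gaps:
unobserved time is not claimed suppressed, so a run abutting an artifact
is truncated there.

## 3. Spectral frames

Per clean segment, a Welch PSD: Hann windows of `welchWindowSec` = 2 s
with `welchOverlap` = 50%, per-channel densities averaged over the four
channels, normalized so the one-sided density integrates to the signal
variance. Two-second windows are the shortest giving 0.5 Hz native
resolution, matching the fixed output grid (`freqGrid`, 0.5–50 Hz in
0.5 Hz steps) onto which each segment's PSD is interpolated; segments
shorter than one window fall back to a single whole-segment window.

Segments are grouped into frames of `frameLen` = 120 s of *concatenated
clean time* (not wall time), so every frame contains a comparable amount
of data; a segment belongs to the frame containing its clean-time
midpoint, and empty frames are omitted. The frame vector is the unweighted
mean of its member segments' PSDs; classification uses log10 power.

## 4. Covariance features on the SPD manifold

Each segment's four channels are filtered into six bands (delta 0.3–4,
theta 4–8, lower alpha 8–12, higher alpha 12–15, lower beta 15–20, higher
beta 20–30 Hz) by brick-wall spectral masks with half-open passbands —
adjacent bands then partition the spectrum, so the band rows sum exactly
to the 0.3–30 Hz-filtered signal — and stacked with the suppression
timeline into a 25-row signal (channel-major within band, bands low to
high, timeline last; the order is serialized with every model).

Per segment, the covariance is estimated with Oracle Approximating
Shrinkage: Σ = (1−ρ)S + ρ(tr S/p)I with the closed-form ρ, which keeps
every estimate symmetric positive definite even for constant rows (a
timeline of all zeros) or short segments. Per-frame matrices are the
elementwise (Euclidean) mean of the member segments' OAS covariances —
SPD, cheap, and adequate at this averaging scale; a Karcher mean per frame
would be the alternative reading.

Geometry uses the affine-invariant metric
δ(A,B) = ‖log(A^{−1/2}BA^{−1/2})‖_F. Matrix functions go through
eigendecompositions with an eigenvalue floor of 1e−12; the Karcher mean
iterates the fixed-point update with step size 1, tolerance 1e−9 and at
most 100 iterations, raising a diagnostic error on non-convergence.

**Riemannian potato.** Frames are screened sequentially: each frame's
distance to a running geometric mean is z-scored against running
(Welford) statistics of the inlier distances; frames with z >
`potatoZ` = 2.5 are flagged and removed from the covariance *and* the
spectral stream. The mean moves by a geodesic step of `potatoAdapt` = 0.1
toward inliers only; the first `potatoBurnIn` = 10 frames are never
flagged. These are literature-typical values; the affine invariance of
the metric makes the screen invariant to global rescaling.

**Tangent projection.** For SVM classification the frames are projected
to the tangent space at a reference point R: v(C) = vectorized upper
triangle (off-diagonals × √2) of log(R^{−1/2} C R^{−1/2}), so that
‖v(C)‖₂ = δ(R, C). R is the *balanced* Riemannian mean — the geometric
mean of the two class means — computed from one patient+frame sampling
draw of the training set, and is stored with the ensemble: new cohorts
are projected to the saved R without any refit. (Computing R from frames
sampled across all saved estimators' draws would be circular, since the
first estimator already needs the projection; one reference per ensemble
matches the single shared tangent space of the design.)

## 5. Classifiers

**Balanced random forest** (patient, patient+burstsupp): 500 trees by
default (`nTrees`), √d features per split, each tree grown on a bootstrap
of the minority class plus an equal-size draw from the majority class, so
the per-tree class ratio is 1:1 at any cohort imbalance. Categorical
agents use fixed vocabularies; unseen levels map to "Other" at prediction
time so frozen models transfer without crashing. The patient probability
is the mean of the per-tree probabilities. Operation length uses the
exact duration.

**Bagged weighted SVMs** (spec, cov): the two-level undersampling scheme
— all minority patients plus a majority subsample of size
max(minority, ⌈majority/3⌉); then `nMajor` = 10 frames per patient
(`nMinor` = 20 for minority-class patients in the covariance stream,
which both balances the frame table and diversifies the minority
covariance pool feeding the reference point). Each draw trains a
soft-margin linear SVM (cost `svmCost` = 1) with class weights inversely
proportional to the frame-class frequencies; the linear kernel on tangent
vectors is the established choice for Riemannian classification, and the
kernel is configurable. The candidate is kept only if its frame-level
AUC-ROC over *all* frames of the full training set reaches the acceptance
threshold (`initialAucThreshold` = 0.70); after `iterPerLevel` = 5
consecutive failures the threshold is multiplied by (1 − `decay`) with
decay 2.5%, guaranteeing termination. `R` = 25 estimators are saved by
default. A decision value of exactly 0 classifies as non-POD. One seeded
generator drives patient then frame sampling in fixed order, so a seed
reproduces the ensemble and its threshold history bitwise.

Patient-level prediction is the mean ratio of frames classified POD over
estimators and frames; no further calibration is applied — the
frame-ratio formula *is* the probability.

## 6. Fusion

Each classifier's g-mean-optimal threshold (g = √(TPR·(1−FPR)); the
square root follows the standard definition) is computed on training
probabilities over the midpoints between consecutive distinct sorted
values, ties toward the smallest threshold, 0.5 for degenerate all-equal
input. For the forest, *out-of-bag* probabilities stand in for training
probabilities — in-sample balanced-forest probabilities are nearly
degenerate and would corrupt the threshold. Four shift subsets are
evaluated (all three classifiers, or each pair with the third shift 0);
shifts are 0.5 − threshold, shifted probabilities are clipped to [0, 1],
and the subset with the highest training AUC of

p_comb = max(p_patient+burst, min(p_spec, p_cov))

is frozen and applied unchanged to test data. When p_m — the mean of the
(shifted) probabilities of classifiers whose training AUC reaches
`aucFloor` (default 0.55; "high enough" is otherwise unspecified) — falls
below 0.25, p_comb = p_m. Ties between subsets keep the fixed preference
order (all, then the pairs). Binary calls use the fixed 0.5 threshold;
NPV = TN/(TN+FN) is reported as missing (not zero) when no negative
calls exist.

## 7. Evaluation protocol

Cross-validation is patient-grouped (all frames of a patient share a
fold) and stratified by POD label within fold — at ~20% prevalence,
unstratified small folds would regularly miss a class. Every trainable
quantity (forests, ensembles, the reference point, thresholds, shifts) is
fit on training folds only; the audit trail records per fold the patient
ids entering each component and an md5 fingerprint of the sorted training
ids. Exclusion rules (clean EEG under 20 min, missing clinical fields)
apply before CV.

Medication-group training fits one full stack per maintenance agent
(Propofol, Desflurane, Sevoflurane) with at least `minGroupSize` = 20
patients and both classes, plus an all-medications stack; smaller or
single-class groups fold into the all-medications stack, and patients on
other or mixed agents are always routed there. Transfer evaluation
applies a frozen grouped set to a new cohort with no refitting:
covariances are projected to the saved reference points and the saved
shifts are applied.

## 8. The synthetic cohort generator

The generator exists because the study data the method targets cannot be
shared; it reproduces the statistical structure the pipeline assumes,
with exact planted ground truth. Per patient:

* **Background**: 1/f ("pink") spectrum realized by spectral shaping of
  white noise (flattened below 0.5 Hz), independently per channel, plus a
  narrow-band alpha oscillation with a per-patient peak frequency drawn
  from 8.5–11.5 Hz. Background and alpha are drawn as one Gaussian
  process with summed spectra — distributionally identical to summing
  independent processes, at half the cost. Channels are independent
  realizations so common-average re-referencing attenuates rather than
  cancels the alpha.
* **Agent dependence**: relative alpha amplitude 0.9 (Propofol, the
  strongest frontal alpha), 0.7 (Sevoflurane), 0.6 (Desflurane), 0.4
  (Other); mean suppression fraction 0.24 / 0.161 / 0.182 / 0.15,
  matching per-agent BSR levels reported for intraoperative cohorts. POD patients' alpha power is
  multiplied by `alphaPowerRatioPod` and their expected suppression
  fraction shifted by `bsrShiftPod` (defaults 0.8 and +0.01 — the
  reference cohort shows only a small overall BSR gap).
* **Amplitude nonstationarity**: a slowly varying lognormal envelope
  (Ornstein–Uhlenbeck on the log scale, τ = 60 s, SD 0.25). Real
  intraoperative EEG is amplitude-nonstationary; without this, the top 1%
  amplitude samples of a stationary process scatter uniformly and the
  per-patient quantile mask would shred every recording into sub-second
  segments.
* **Suppression**: alternating-renewal episodes (exponential durations,
  minimum 2 s, capped at 25 s) attenuating all channels by ×0.05, placed
  with ≥1 s isolation, trimmed to hit a target fraction exactly; an
  episode of an exact requested length can be planted for recovery tests.
  The ground-truth fraction is defined relative to artifact-reduced time,
  the same denominator as the BSR.
* **Artifacts**: isolated rectangular spikes of 10× the patient's 99%
  amplitude quantile lasting 0.1–0.5 s (the events the quantile mask must
  catch), plus broadband EMG/movement-like bursts of 2–8 s at 5–9× RMS
  whose rate is tied to `artifactRate`. The bursts dominate the amplitude
  tail, putting the 99% quantile threshold above the normal signal — the
  regime the amplitude filter is designed for on real, artifact-laden
  recordings. Both artifact types keep ≥2 s clear of suppression episodes
  so that segment edge padding cannot truncate a planted suppression run.
* **Clinical covariates**: Gaussian age and operation length, ordinal ASA
  (rounded latent Gaussian, clipped to 1–4), Bernoulli benzodiazepine,
  with POD class offsets defaulting to the reference-cohort gaps
  (age +2.7 y, ASA +0.24, OP length +1.27 h) — a deliberately weak
  clinical effect.
* **Scale**: default sampling rate 128 Hz (typical for frontal anesthesia
  monitors) and recording lengths 20–30 min. Real operations run for
  hours; the shortened recordings keep desk-scale benchmarks tractable
  and still give 10–15 two-minute frames per patient. All cohort-level
  and patient-level draws derive from one master seed, so a cohort is
  bit-reproducible and can be streamed patient by patient.

What the generator does **not** emulate: pharmacodynamics and drug dosage,
event markers, eye/EMG artifact morphology beyond amplitude, inter-channel
anatomical correlation structure, non-Gaussian microstructure of real EEG,
and any direct coupling between clinical covariates and EEG dynamics.
Passing benchmarks on these cohorts therefore demonstrates that the
pipeline recovers planted effects of realistic size through the full
preprocessing and classification chain — not that it attains any
particular performance on real patients.

## 9. Problem sizes used in the shipped benchmarks

The packaged tests and `scripts/acceptance.R` use cohorts of 240 patients
(≈20% POD), 2 repeats of stratified 5-fold cross-validation, ensembles of
R = 8 estimators and 300-tree forests, and a 100-patient transfer cohort
whose clinical covariate distributions are shifted (age +4 y, OP length
+1 h, class offsets removed) while the planted EEG effect is unchanged —
the configuration in which a covariate-only classifier should fail to
generalize while the EEG-based fusion remains robust. These sizes were
chosen as the smallest at which the class effects are resolved clearly;
all of them are ordinary function arguments.

## 10. Known limitations

* Published clinical pipelines of this kind rarely specify their
  segmentation and suppression detectors in full; the detectors here are
  conventional constructions with every parameter exposed in
  `podConfig()` rather than fixed.
* Whether per-frame covariance averaging should be Euclidean or
  Riemannian is an open reading; Euclidean is used.
* The frame clock runs over concatenated clean time; wall-clock framing
  is the alternative reading and would change frame counts for heavily
  artifacted recordings.
* EDF export quantizes to 16 bits; round trips are exact only to
  quantization precision.
* With a single-digit number of POD patients in a fold, fold-level AUCs
  are noisy; the shipped benchmarks therefore report means over repeats
  and folds.
* The max/min fusion is not robust to *uninformative* EEG classifiers:
  when the EEG carries no class signal at all, min(p_spec, p_cov) is pure
  noise centered well above the forest's probability for low-risk
  patients, and the max() lifts their ranks — on such cohorts the
  combined AUC falls measurably below the patient-only AUC rather than
  collapsing onto it. The fusion rule has no pathway to discard an
  uninformative classifier (the training-AUC floor guards only the
  low-probability override, and the in-sample frame ratios of the
  undersampled ensembles are optimistic by construction, since minority
  patients are in-sample for every estimator). In practice this matters
  only in the no-signal regime.
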