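---
title: "Screening for occult paroxysmal AF from sinus-rhythm Holter ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for occult paroxysmal AF from sinus-rhythm Holter ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Paroxysmal atrial fibrillation (pAF) is intermittent by definition: a patient
can carry the arrhythmia yet show nothing but sinus rhythm on the 24-hour
Holter recording that was meant to find it. The detection rate of new-onset AF
on a single 24-hour Holter is low, while prolonged or implantable monitoring is
costly and invasive. Two indirect signatures of the pAF substrate are, however,
present even in AF-free recordings: subtle atrial (P-wave) morphology changes,
and an elevated burden of supraventricular ectopy (SVE). `holterpaf`
implements a two-stage learning pipeline that screens AF-free 24-hour Holter
recordings for these signatures and flags patients likely to harbour occult
pAF, together with the SVE-burden comparator it is benchmarked against and a
synthetic cohort simulator that makes the whole chain testable without
clinical data.

## The two-stage model

A 24-hour, 3-channel recording at 128 Hz holds about 11 million samples —
far too long for a single network. The pipeline therefore splits learning in
two:

1. **Segment stage.** The recording is cut into non-overlapping 7-s segments
   (3 × 896 samples). Each segment is Z-normalised per channel, transformed
   with a short-time Fourier transform (window 50 samples, hop 25, Hann
   window, `log(1 + |X|)` magnitude, giving a 26 × 34 spectrogram per
   channel), and scored by a residual convolutional network trained with
   binary cross-entropy on *segment-wise* labels: every segment of a pAF
   patient is positive, every control segment negative. The network is three
   residual blocks — each two (convolution → batch norm → ReLU) modules with
   an identity skip, a 1×1 projection where the channel width changes —
   separated by 2×2 average-pool downsampling, then global average pooling
   and two fully connected layers yielding a latent embedding and one logit.
2. **Patient stage.** Each patient's segment embeddings, in temporal order,
   are pooled into a fixed-length feature vector: the recording span is
   divided into `B` equal clock-time bins (default 24, one per hour of a
   24-hour exam) and each bin contributes its mean latent vector, mean
   segment probability, segment count and an empty-bin flag; a global block
   adds the mean/max/SD of segment probabilities, the fraction of
   SVE-containing segments and the total segment count. A gradient-boosted
   tree ensemble maps this vector to the patient-level pAF probability.

The division of labour is deliberate: the network learns the short-range
waveform regularities it is good at, while the boosted trees — which cope far
better with a few hundred patients than a deep network would — integrate the
whole recording, including time-of-day structure. The segment-level score
alone (the "encoder-only" ablation emitted by every experiment) is
consistently weaker than the patient-level score, which is the entire point
of the second stage.

### Preprocessing chain

* **Ectopy excision.** Around every annotated ventricular ectopic beat, 3.5 s
  forward and backward are removed (a 7-s window, which also discards the
  T-wave turbulence that follows ventricular ectopy). Overlapping windows
  merge. Two settings mirror the two published analyses: setting 1 keeps
  SVE-containing segments (flagged `contains_sve`); setting 2 additionally
  excises ±3.5 s around every SVE beat, leaving pure sinus rhythm.
* **Segmentation.** Each remaining interval is tiled from its start with 7-s
  windows; trailing remainders are discarded. The stride/phase is not
  specified by the protocol this mirrors; non-overlapping tiling from the
  interval start keeps segment counts interpretable.
* **Noise gate.** A deterministic, rule-based gate drops flatline channels
  (variance < 1e−6 mV²), saturated channels (> 5 % of samples at ±5 mV) and
  out-of-range segments (> 8 mV). This replaces manual/learned noise review
  with an auditable rule; every threshold is an exposed argument and every
  drop is counted in the removal log.
* **Diurnal tagging.** Night is the fixed half-open window [22:00, 07:00);
  a segment's tag is decided by its start time, which is unambiguous for
  windows straddling a boundary. `run_experiment(period = "DAY"/"NIGHT")`
  restricts both training stages to one period while keeping the same
  patient folds as the all-day run.

### Evaluation protocol

Patients are assigned to 5 stratified folds at the patient level; all segments
of a patient travel with it, so test patients are never seen in training (the
encoder's early-stopping validation split is also patient-wise, inside the
training fold). Reported metrics: AUROC (rank-based Mann–Whitney, ties at ½),
and sensitivity/specificity/PPV/NPV/F1/F2 at the Youden-style cutoff that
maximises sensitivity + specificity over observed scores (ties broken toward
higher sensitivity, then the lower threshold; prediction is positive at
`score >= cutoff`). Model metrics carry fold-based 95 % CIs
(mean ± t·SD/√k over the per-fold values, each fold at its own Youden cutoff);
the SVE-burden baseline carries 1000-replicate percentile-bootstrap CIs over
patients — mirroring the asymmetric CI methodology of the protocol this
reimplements. Both the fold-mean and the pooled-prediction AUROC are emitted.

The elapsed-time analysis reports, among pAF patients, the detection rate at
the chosen cutoff within strata split at T ∈ {3, 6, 12, 36} months between
the index date (first AF documentation) and the Holter exam. Months are 30.44
days and a patient at exactly T joins the "< T" stratum; both conventions are
arguments.

### The SVE-burden baseline

The comparator scores each patient by the fraction of their 7-s segments
(setting-1 preprocessing, since setting 2 removes the signal by construction)
that contain at least one SVE beat, used directly as the pAF probability.
AUROC being rank-based, any monotone transform of the burden gives the same
result.

## The synthetic cohort simulator

No clinical recordings ship with the package, so `generate_cohort()` writes
WFDB cohorts whose statistical structure carries exactly the two information
channels the method assumes:

* beats are parametric P-QRS-T templates (Gaussian lobes, per-channel
  projection weights), placed at RR intervals set by a smooth diurnal
  heart-rate profile (cosine-blended plateaus: night 23:00–06:00, day
  08:00–21:00, 2-h transitions) times multiplicative log-normal jitter;
* SVE beats arrive by Poisson thinning at a per-class hourly rate, fire early
  and carry a diminished P wave; VE beats are wide, P-less and discordant;
* pAF patients receive a fractional P-duration prolongation (with a matching
  amplitude reduction), drawn per patient around `1 + p_wave_effect` with
  between-patient SD `p_duration_sd`;
* Gaussian noise of `noise_sd` mV is added throughout, and every beat is
  annotated with its true class.

Defaults describe a desk-scale screening cohort: 60 patients, 128 Hz,
day/night heart rates 75/58 bpm, control SVE rate 20/h vs 60/h in pAF,
VE 5/h, noise 0.04 mV, P-duration effect 0.2 with SD 0.06. The pAF class
fraction defaults to 0.25 — higher than the ~12 % prevalence of the clinical
setting — so that stratified 5-fold splits of small cohorts keep enough
positive patients per fold; prevalence is one argument away. Elapsed times
for pAF patients are drawn from an equal-weight mixture of uniform strata
bounded at {1, 3, 6, 12, 36, 48} months, which guarantees patients on both
sides of every cutoff of the elapsed-time analysis. The whole cohort is a
pure function of the configuration including its seed, byte-identically.

What the simulator deliberately does **not** model: fibrillatory waveforms
(the cohorts are AF-free by design, as in the screening setting), motion and
electrode artifacts beyond Gaussian noise, respiratory modulation,
time-varying substrate (the morphology shift is constant across the
recording, so a day-vs-night contrast in *signal content* cannot be
synthesised, only the mechanics of the diurnal split can be exercised), and
any biophysical realism of the waveforms themselves. A green test suite
therefore demonstrates that the pipeline recovers planted, correctly
structured signal and stays at chance when none exists — not that the
clinical effect sizes are reproduced; the published real-cohort figures
cannot be recomputed because that dataset is not public.

## Numerical and design choices

* **WFDB I/O.** Records are 16-bit MIT format with per-channel gain/baseline
  (default 200 ADU/mV), so round-trips are exact to half a quantisation step;
  annotations use the standard two-byte words with SKIP encoding for long
  gaps. Beat-code mapping is fixed: N/L/R → NORMAL, A/a/J/S → SVE, V → VE,
  everything else → OTHER (the annotation dialect of the original Holter
  software is not documented; this is a declared convention). The recording
  start time comes from the header base time — it anchors the diurnal split —
  and the manifest must supply it if absent.
* **Encoder training.** Adam, binary cross-entropy, early stopping on
  patient-wise validation loss (patience 5 by default), best-epoch weights
  restored. Convolutions are im2col + BLAS matrix multiplications with a
  channel-first layout; the backward-data pass is a convolution with flipped
  kernels; all gradients are finite-difference-checked in the test suite.
  Batch-norm evaluation uses running statistics, which is what makes scoring
  batch-size-invariant. The default architecture ([16, 32, 64] channels, 3×3
  kernels, latent 32, batch 1024, learning rate 1e−4) is configurable; the
  exact widths are a design choice, as only the three-residual-block shape is
  fixed by the protocol.
* **Desk-scale configurations.** Tests and the acceptance script run reduced
  problem sizes chosen as the package's own test conditions: cohorts of
  12–60 patients with 5–20-minute recordings, an [8, 16, 32]-channel encoder
  with latent 16, batch 128, learning rate 1e−3, up to 8 epochs, 25–30
  training segments per patient, 2–5 folds, and a boosted-tree stage of 300
  depth-2 trees at shrinkage 0.05 with column subsampling 0.7 (small patient
  counts favour shallow, strongly regularised ensembles). All published-scale
  constants (7 s, 128 Hz, window 50, ±3.5 s, 22:00–07:00, k = 5, 1000
  bootstrap replicates, batch 1024, learning rate 1e−4) remain the package
  defaults.
* **GBM details.** `min_child_samples` is specified in samples; xgboost's
  `min_child_weight` is a hessian sum, which for logistic loss is at most ¼
  per sample, so the count is converted by that factor. The optional random
  search (off by default) replaces the published Bayesian/bandit tuner,
  whose identity is orthogonal to the method.
* **Feature vector.** How variable-length latent sequences become a fixed
  GBM input is not specified by the protocol; binned temporal pooling plus
  global summaries was chosen because it honours temporal order with a fixed
  dimension. Segment probabilities are pooled alongside latents — the
  classification head is trained information and discarding it would be an
  arbitrary loss. Patients with zero surviving segments yield the all-zero
  vector with every empty-bin flag set, which predicts without error.
* **Degenerate inputs.** Zero-variance channels Z-normalise to zeros rather
  than NaN; undefined contingency ratios (empty denominators) are reported
  absent, not zero; F-beta is 0 by convention when precision and recall are
  both 0; bootstrap replicates missing a class are redrawn with bounded
  retries; a patient with no segments is excluded from the burden baseline
  with a warning.
* **STFT conventions.** Only the window size (50) is fixed by the protocol;
  Hann windowing, hop 25, no padding and `log1p` magnitude are package
  choices, all exposed as arguments. With a Hann window a pure bin-centred
  tone concentrates its energy in the bin and its two neighbours, and the
  tests assert both that concentration and exact agreement with a directly
  computed windowed DFT.

## Known limitations

* The encoder is CPU-bound pure R; it trains small spectrogram models in
  minutes but is not suited to the published scale (8.5 million segments,
  batch 1024) — the architecture is faithful, the throughput is not.
* The simulator's two information channels are planted independently; real
  atrial remodelling presumably couples morphology, ectopy and timing in ways
  no parametric template reproduces.
* Output probabilities are not calibrated (ranking metrics only), and no
  formal AUROC-difference test is provided — neither is part of the protocol
  this package implements.
* Setting-1 SVE segments are kept verbatim; whether the original analysis
  modified reannotated SVE events in setting 1 is not documented, and
  "recordings from patients with confirmed pAF" is the interpretation used
  for segment labelling.
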