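---
title: "Quantifying dysphonia in telephone-quality sustained vowels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dysphonia in telephone-quality sustained vowels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parkinson's disease degrades speech in most patients: vocal fold cycles
become irregular (jitter, shimmer), turbulent aspiration noise increases,
and pitch control weakens. A sustained vowel /a/, held "as steadily and
for as long as possible", isolates these phonatory impairments from
linguistic content, so it can be collected over an ordinary telephone
line at population scale. The price is telephone-quality audio: 8 kHz
sampling (useful spectrum only to 4 kHz), a 300–3400 Hz passband that
deletes the fundamental for most voices, 16-bit quantization, and
uncontrolled acoustic conditions.

`pdvoice` implements the full analysis chain for this setting: synthetic
phonation generation with known ground truth, a telephone-channel model,
automated quality screening, fundamental-frequency (F0) tracking, a
304-measure dysphonia battery in 13 families, margin-based feature
selection with cross-validated vote aggregation, and a balanced-training
/ unbalanced-held-out classification protocol whose split arithmetic
matches the published cohort (1987 PD / 9955 control phonations; a
3000-recording balanced subset; an 8942-recording held-out remainder
with 487 PD and 8455 controls). The real study recordings are
confidential, so every claim the package tests is made on synthetic data
whose generative parameters are known exactly.

## The synthetic phonation generator

The generator is a source–filter model built for *verifiable ground
truth* rather than naturalness:

* **Source.** A Rosenberg-type glottal flow pulse (raised-cosine opening
  over 40% of the cycle, cosine closing over 16%). Cycle `i` starting at
  `t_i` has period `T_i = (1/f0(t_i)) (1 + j e_i)` with `e_i` i.i.d.
  standard normal and `j` the jitter level; its peak amplitude is
  `A_i = 1 + s n_i` with `s` the shimmer level. The pulse *shape*
  follows the slow, unjittered period while the cycle *onsets* carry the
  jitter — otherwise the waveform's peak-to-peak intervals would be a
  two-point moving average of the periods and realized jitter would be
  understated by a factor of ~2 relative to the recorded ground truth.
  The pressure signal is the derivative of the flow (lip-radiation
  characteristic), which gives the sharp glottal-closure excitation that
  the noise families (GNE in particular) rely on.
* **Filter.** Cascaded second-order resonators at conventional adult /a/
  formants (710, 1100, 2540 Hz; bandwidths 80, 90, 120 Hz). These are
  configuration values, not physiological claims.
* **Noise.** Band-limited Gaussian aspiration noise added at a specified
  RMS ratio to the voiced signal. Slow sinusoidal F0 tremor is available
  (`tremor_extent`, `tremor_rate`).
* **Channel.** Synthesis runs at 44.1 kHz; `apply_telephone_channel()`
  then resamples to 8 kHz, band-limits to 300–3400 Hz with a zero-phase
  order-3 Butterworth filter, optionally adds channel noise at a given
  SNR, and quantizes to 16 bits. Codec-specific artefacts (GSM/AMR) are
  out of scope; the model follows the generic down-sample / band-limit /
  noisy-channel description.

Every recording returns its realized cycle times, periods and
amplitudes, so estimator error can be measured against truth rather than
against another estimator.

What the generator does *not* emulate: room acoustics and device
variability, articulatory drift, voice breaks and diplophonia,
correlated (non-i.i.d.) perturbation sequences, and any physiological
link between disease state and acoustics. Default synthetic cohorts give
the PD class elevated perturbation means (2x the control means) purely
so that class signal exists; passing tests therefore demonstrate that
the *pipeline* works — recovery of known perturbations, selection of
known informative features, correct protocol arithmetic — not that the
published discrimination accuracy is reproduced, which would require the
confidential recordings.

## Quality screening and segment selection

`screen_quality()` reconstructs an automated exclusion step with
config-exposed thresholds: duration >= 2.5 s, voiced fraction >= 0.6,
clipping fraction <= 0.01, SNR estimate >= 10 dB. The SNR estimate
treats power above 3 kHz as a white-noise floor extrapolated across the
band — crude, but deterministic and gain-invariant (clipping detection
is amplitude-referenced by design).

`select_stationary_segment()` implements the most-stationary-2 s rule:
among all 2 s windows aligned to the 10 ms contour grid, take the one
minimizing the SD of F0, ties to the earliest. Two calibrations are
ours: a candidate window needs only >= 75% voiced frames (severely
jittered voices drop isolated frames below the voicing threshold
without invalidating a segment), and the dispersion is computed over
the voiced frames. A brute-force minimizer over all windows is kept as
a test oracle.

## Pitch: sawtooth-inspired spectral matching

`estimate_f0_contour()` works on a 10 ms grid. Per frame the square-root
magnitude spectrum (Hann window of 4 periods of `f_min`, ERB-scale
interpolated at 0.05 ERB) is matched against kernels with cosine lobes
at each candidate's prime-numbered harmonics (weights `1/sqrt(h)`;
candidates log-spaced at 1/96 octave in 50–500 Hz), retaining the
negative cosine regions between harmonics so that octave-up candidates
are penalized by the energy they leave in their valleys. The winning
candidate is refined parabolically on the log-frequency grid.

Two practical layers sit on top:

* **Voicing strength** is a harmonic-contrast ratio computed in a
  second, pitch-matched pass (window of 8 periods, first 3 harmonics):
  energy under the positive lobes minus energy in the valleys, over
  their sum. On this scale broadband noise scores ~0.1, clean voice
  >= 0.5, and heavily jittered but clearly voiced phonation ~0.3; the
  default voicing threshold is 0.2. (The classical 0.3 convention
  belongs to a different strength statistic; with our ratio it marks
  severely jittered voices unvoiced, which is why the default differs.)
* **Temporal continuity.** With the fundamental deleted by the telephone
  passband, a formant-supported wrong candidate can win isolated frames
  (e.g. ~350 Hz when 2x the candidate lands on the 710 Hz formant).
  Frames deviating more than 25% from the median pitch of the
  highest-contrast frames are re-localized among candidates within
  +/-25% of that reference. A 120→180 Hz ramp stays inside the band, so
  legitimate slow variation survives.

`extract_cycles()` places one mark per period by picking the dominant
polarity-normalized waveform peak in a window 0.7–1.3 times the current
period ahead, with parabolic sub-sample refinement (the period is a
non-integer number of samples at 8 kHz; without refinement the
quantization noise would swamp small jitter). The "current period" is a
running median of the last five accepted periods, bounded to 0.7–1.4
times the contour median, so isolated contour glitches cannot derail the
tracker; marking stops 15 ms short of the signal edges where zero-phase
filter transients distort peaks. On telephone-degraded synthetic
phonations this recovers local jitter within a few percent of ground
truth across jitter levels 0.005–0.04.

## The 304-measure battery

The thirteen families and their frozen sizes: jitter variants (28),
shimmer variants (21), HNR/NHR (4), glottis quotient (3), GNE (6), VFER
(9), EMD excitation ratios (6), MFCC (39), F0-vs-normative comparisons
(3), wavelet contour measures (182), PPE, DFA, RPDE (1 each). The
per-variant enumerations inside the jitter, shimmer and wavelet families
are fixed by this package (the classical measures are mandatory;
systematic aggregation x transform x source-sequence variants fill each
family to its size) and frozen in `feature_manifest()` — names and order
never depend on the input.

* **Jitter (28).** Five statistics (local, absolute, RAP, PPQ5, DDP)
  with mean and median aggregation on two sources (cycle periods, 10 ms
  frame F0 values; 20 measures), four un-normalized log-period variants,
  and TKEO mean/SD of each source normalized by its squared mean (4).
* **Shimmer (21).** Local, dB, APQ3/5/11, DDA with both aggregations
  (12); un-normalized log-amplitude local/APQ3/APQ5 (3); the same three
  on the 25 ms frame RMS-energy sequence (3); TKEO mean/SD of the
  amplitude sequence (2); raw mean absolute difference (1, the one
  declared amplitude-referenced measure).
* **HNR/NHR (4).** Per 50 ms frame, `r` is the maximum normalized
  autocorrelation in a lag window around the frame period, with
  parabolic refinement of the lattice maximum (the true period is a
  fractional lag; without refinement clean HNR saturates ~10 dB low);
  HNR = 10 log10(r/(1-r)), NHR = (1-r)/r, mean and SD over frames.
* **GQ (3).** Relative SD, 5–95 percentile range, and the fraction of
  cycles deviating more than 5% from the median period.
* **GNE (6).** 13th-order LPC inverse filtering per 50 ms frame; Hilbert
  envelopes of the residual in 1000 Hz bands centered every 500 Hz (up
  to 3.5 kHz — adapted from the original 10 kHz formulation to the 8 kHz
  telephone rate); GNE is the maximum envelope correlation over band
  pairs >= 1500 Hz apart and inter-band lags up to 0.4 ms. SNR variants
  map the correlation through 10 log10(r^2/(1-r^2)), once on raw
  envelopes and once on TKEO-processed envelopes.
* **VFER (9).** Spectrum split at 2.5 kHz ("signal" below, "noise"
  above, bounded by the 4 kHz Nyquist limit of telephone material):
  band-energy, TKEO-energy and spectral-entropy ratios as frame
  mean/SD plus whole-segment aggregates.
* **EMD-ER (6).** Sifting with the classical SD < 0.2 stopping rule;
  "noise" is the sum of the first two intrinsic mode functions, the
  remainder is "signal"; energy, TKEO and entropy ratios raw and in dB.
  One caveat is worth stating plainly: at 8 kHz the voiced energy rides
  the ~700 Hz first-formant carrier, which a faithful decomposition
  assigns to the first IMFs, so the "noise" side contains much of the
  voiced signal. The ratios remain deterministic and informative as
  features, but their *direction* does not track breathiness the way it
  would for wideband studio recordings; the tests therefore validate
  the definition against an analytic multi-tone oracle rather than a
  clean-vs-noisy ordering.
* **MFCC (39).** 25 ms Hamming frames, 10 ms hop, 26 mel filters over
  0–4000 Hz, orthonormal DCT-II coefficients c0–c12 plus central first
  and second differences, each trajectory averaged over frames. Gain
  changes move only c0.
* **F0-related (3).** z-score of mean log-F0 against a per-gender
  normative log-F0 table (defaults: male 120 Hz, female 200 Hz, SD 0.15
  log-units — replaceable configuration, and gender-only rather than
  age-banded), its two-sided Gaussian tail probability, and the ratio
  of observed to normative log-F0 SD.
* **Wavelet (182).** The voiced contour and its log, each linearly
  detrended and zero-padded to 1024 samples, through a 10-level
  periodized db8 transform; per band (10 detail + 1 approximation): log
  energy, coefficient entropy, log-energy entropy, TKEO mean/SD, max
  absolute coefficient, IQR, SD; plus three per-input global statistics
  (log total energy, band-energy entropy, detail/approximation ratio).
  Zero-padding after detrending keeps all 10 levels defined for the
  200-frame contour of a 2 s segment.
* **PPE.** Semitone contour relative to its median, whitened by an
  order-2 linear predictor (absorbing natural smooth variation);
  normalized entropy of the residual histogram (+/-12 semitones, 60
  bins). 0 for constant contours by definition.
* **DFA.** Scaling exponent over box sizes log-spaced in 50–1000
  samples; the battery reports the logistic-mapped exponent
  `1/(1+exp(-alpha))`, with the raw exponent available via
  `dfa_exponent()` (white noise 0.5, random walk 1.5).
* **RPDE.** Time-delay embedding m = 4, tau = 7 samples, ball radius
  0.12 x embedded SD, return times up to 1000 samples; normalized
  entropy of the first-return-time histogram. Exactly 0 for strictly
  periodic signals whose period is coarse enough to resolve on the
  sample lattice.

`extract_all()` concatenates the families in the fixed manifest order
and errors (with the family name, condition class `pdvoice_flag`) if any
measure is non-computable — recordings are flagged, never silently
imputed.

## Feature selection and classification

Three rankers over standardized features: Gram–Schmidt orthogonalization
forward selection (squared correlation with the +/-1 label vector,
selected directions projected out), ReliefF (10 nearest hits/misses,
range-normalized), and SIMBA (hypothesis-margin gradient ascent, linear
utility, 5 passes, learning rate 0.1 decaying as 1/sqrt(t); the per-step
nearest-neighbour scan is compiled). Per-run top-30 lists are aggregated
by `vote()`: one vote per appearance, ties by mean within-run rank, then
by index. Votes are counted over the training folds of the CV runs — the
aggregation level is our choice, matching the top-30 search restriction.
A 30-component PCA projection (fit on training data only) is provided as
the feature-transformation alternative.

Classifiers follow the published configurations: RBF-SVM with features
scaled to [-1, 1] on training data only and a (C, w) grid of 2^-5..2^15
by 2^2 times 2^-15..2^3 by 2^2 (the printed C grid has an inconsistent
step; we read it as symmetric with the w grid); random forests with
500/1000 trees and 0.5/1/2 x sqrt(p) feature sampling; discrete AdaBoost
over depth-2 trees with 1000 learners and learning rates 0.01–0.5.
Hyper-parameters are chosen by inner 5-fold CV on the highest mean
balanced accuracy (ties: smaller C, then larger w / fewer trees /
smaller rate); the inner-loop protocol is not specified by the study, so
5-fold is our default. Trained models store their scaling parameters and
feature manifest and refuse to predict on mismatched features.

The two-step protocol: `make_split()` draws 1500 recordings per class
(uniform, without replacement) into the balanced set; the remainder is
held out. The sampling unit is the recording, matching the protocol's
wording, although participants contribute several phonations — a
subject-wise mode (`by_participant = TRUE`) is provided, and without it
a participant can legitimately appear on both sides of the split, a
leakage route inherited from the design itself. `run_cv()` runs
stratified 10-fold CV (stratification within the balanced set is
harmless and stabilizes small folds) for a configurable number of
iterations, ranking features on each training fold only and training on
the top-k for k = 1..30; `chosen_k` is the smallest k whose mean
balanced accuracy is within one SD of the maximum (the study picked its
k by inspecting the curve; the one-SD rule is our reproducible stand-in).
`finalize_and_validate()` re-ranks on the full balanced set, trains the
final model, and evaluates once on the held-out set, refusing any id
overlap.

## Numerical choices and problem sizes

Degenerate inputs flag rather than impute: too few cycles, non-positive
amplitudes, LPC failure, < 3 IMFs, constant signals for DFA/RPDE, no
recurrences. Entropies use the convention 0 log 0 = 0; band energies add
1e-300 guards before logs; autocorrelation r is clamped to
(1e-12, 1 - 1e-12).

The test suite and the acceptance script exercise the pipeline at
reduced, fixed problem sizes chosen to make the statistical checks sharp
on a desktop: 3–5 s phonations, 20 seeds per perturbation level for
recovery and monotonicity checks, 600-recording balanced cohorts with 5
informative features among 304 for selection recovery, and 10-fold CV
with 5 iterations for the end-to-end run; the full-scale split
arithmetic (11,942 recordings) runs on cohort metadata, which is exact
at any scale. The study-scale profile (100 CV iterations over the full
feature matrix) uses the same functions with larger arguments.

## Known limitations

* The synthetic cohorts cannot validate clinical discrimination
  accuracy; they validate the machinery.
* The pitch tracker assumes one sustained voice; it is not a general
  speech F0 tracker (no voicing onsets/offsets model, no dynamic
  programming).
* The jitter/shimmer/wavelet variant enumerations are this package's
  frozen reconstruction of family sizes that the literature reports
  only as totals.
* GNE is adapted to the 8 kHz rate; published GNE values for wideband
  recordings are not directly comparable.
* EMD-ER direction at telephone band, as discussed above.
* The QC thresholds are reconstructions; the original exclusion
  algorithm is not public.
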