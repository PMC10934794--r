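---
title: "Multidimensional QRS detector benchmarking: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional QRS detector benchmarking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsbench)
```

## The evaluation problem

A QRS detector turns an ECG sample stream into a sequence of R-peak
instants. The usual accuracy report — sensitivity and positive
predictivity at some unstated matching tolerance — hides two things that
matter in practice: *how precisely in time* the detector places its
marks, and *how the placement degrades* with muscular noise and with
unusual beat morphologies. `qrsbench` evaluates detectors along all
three axes at once:

* **Detection temporal tolerance (DTT).** A detection within
  `tolerance_samples` of an annotated beat counts as a true positive
  (TP); an annotation left unmatched is a false negative (FN), a
  detection left unmatched a false positive (FP). As the tolerance
  shrinks, each TP that falls out converts into one FN *and* one FP, so
  TP is nondecreasing in the tolerance — the property the DTT sweep
  measures. The default grid is 3, 17, 31, 45, 59 samples, i.e. 8.33 to
  163.89 ms at 360 Hz.
* **Added muscular noise.** A noise waveform is scaled and added to each
  record to reach target signal-to-noise ratios of 15, 7 and 3 dB,
  alongside the untouched record ("no added noise" — real records
  already carry intrinsic noise, so there is no noise-free reference).
* **QRS morphology.** Scores are stratified over the six most frequent
  beat classes of the MIT-BIH Arrhythmia Database: normal (N), left and
  right bundle branch block (L, R), premature ventricular (V), paced
  (P), and atrial premature (A). Together they cover 97.8% of the
  database's beats.

The headline statistic is the true-positive-to-total-beats ratio
(TP/TB) per stratum; Se, PPV, F1 and DER = (FN+FP)/TB are available
through `qrs_metrics()`.

## Matching

`match_detections()` computes a maximum-cardinality one-to-one pairing
under the constraint |detection − annotation| ≤ tolerance, with a sorted
two-pointer scan. For points on a line with a symmetric tolerance this
greedy scan is optimal; the test suite cross-checks it against an
exhaustive augmenting-path bipartite matcher on hundreds of random
instances. Design points worth stating:

* The tolerance is two-sided and inclusive: "3 samples" admits offsets
  in −3..3.
* Ties break toward the earlier detection; the matcher is deterministic.
* Matching always runs against the **full** annotation set;
  morphology stratification (`stratify_matches()`) only filters the
  tally afterwards. A detection near a beat of an excluded class can
  therefore never be re-counted as a hit for another class.
* Strata with TB = 0 are excluded, not scored as 0 or 100.

Summary tables (`aggregate_tp_tb()`) pool counts over records first
(summing TP and TB per stratum), then report the mean and *population*
standard deviation over the pooled stratum values: 6 morphologies × 4
noise levels = 24 values per (algorithm, DTT) cell, 20 per (algorithm,
morphology) cell, 30 per (algorithm, noise) cell. Whether such summary
statistics should pool over records or average per-record ratios is a
genuine convention choice; pooling weights records by their beat counts
and is the default here, and the per-record reports
(`per_record_report()`) expose the unpooled numbers.

## Noise mixing

The signal and noise "powers" are mean squared first differences,
$$P = \frac{1}{N-1}\sum_{i=0}^{N-2}(x_{i+1}-x_i)^2,$$
which ignores DC level and slow baseline drift — sensible when the
quantity of interest is the high-frequency muscular artifact relative to
QRS slopes. Two dB conventions are implemented because the source
formulas for this procedure are not mutually consistent: the printed
relative SNR applies a factor 20·log10 to a ratio of (difference)
powers, and the printed scaling factor is $k=\sqrt{tSNR/eSNR}$ — a
square root of a ratio of *decibel values*, which is dimensionally
unusual and only defined for positive dB values. `qrsbench` therefore
exposes:

* `mode = "as-printed"` — the literal formula, default for fidelity;
* `mode = "power-consistent"` — solves for the k that actually achieves
  the target, $k = 10^{(eSNR-tSNR)/40}$ under the 20·log convention.
  The invariant `relative_snr(Ps, difference_power(k·noise)) == tSNR`
  holds to floating-point precision and is asserted in the tests.

Neither reading is claimed to be the intended one; the harness and the
fixture use the power-consistent mode because only it produces mixtures
whose measured SNR equals the nominal level. The noise record is tiled
end-to-start when shorter than the ECG and truncated from sample 0 when
longer; sampling-rate mismatches are an error (no resampling — both
source databases run at 360 Hz).

## The four detectors

All detectors consume physical-unit samples and return strictly sorted
0-based sample indices with at least 200 ms between detections (the
refractory period, asserted on every run). None applies a group-delay
back-correction: where a detector's decision signal peaks away from the
R apex, the offset is visible in the DTT sweep, which is precisely what
the sweep is for. Moving averages and the band-pass are implemented
zero-phase (centered windows, forward-backward filtering), so the
offsets that remain are properties of the decision logic, not of filter
delay.

**Algorithm 1 — decaying threshold.** Feature:
square(MWA(first difference)), computed in exactly that order. The
three-state machine searches a 260 ms window for the feature maximum
when the threshold is crossed, waits 200 ms, then decays the threshold
exponentially (time constant 200 ms) from `c ×` mean feature amplitude
of all prior R-peaks (c = 0.5; the first threshold is seeded from the
feature maximum over a 2 s learning span, while scanning still starts at
sample one so early beats are detectable). The moving-average window is
the parameter that fixes where detections land: with a causal window of
length W the feature approximates $(x(t)-x(t-W))^2$, which has one lobe
at the upstroke and one W later. The default W = 36 ms — the QRS
rise-time scale — keeps both lobes within ~15 samples of the apex for
all six morphologies; a window much wider than the QRS (say 130 ms)
makes the detected position bistable between two lobes ~47 ms apart.

**Algorithm 2 — dual moving-average paths.** The trigger path
u = |x − MA₂₈(x)| opens a 200 ms search window when it crosses the
adaptive threshold; the R-peak is the argmax of the low-cutoff path
y = |x − MA₁₁₀(x)| inside the window; a 200 ms wait follows. The
threshold update is a convex combination (weights 0.7/0.3) of the
previous threshold and a *fraction* (0.4) of the last R amplitude on y.
The fraction is load-bearing: u's QRS excursion is strictly below the y
amplitude — about half of it for wide ventricular and paced complexes —
so a threshold converging to the full R amplitude would rise above every
trigger excursion and the detector would stall after a few beats. 0.4
places the steady-state threshold safely below wide-complex excursions
while staying far above P/T-wave residue in u. Every stage is
homogeneous of degree one, so detections are exactly invariant under
amplitude scaling (tested).

**Algorithm 3 — level-crossing sampling.** `lc_adc_sample()` simulates
an LC-ADC with asymmetric hysteresis: 2^M − 1 levels uniformly spanning
the record's amplitude range (M = 8); an event is emitted at every level
crossed in the direction of the previous event, and against that
direction only after k_l = 4 levels of travel from the last event
(chatter suppression). A sample lying exactly on a level counts as a
crossing in the direction of motion. Events carry the level index,
direction, a token bit, the inter-event interval modulo 2^11 ticks (the
hardware counter width), and — for evaluation only — the absolute
sample. Direction-reversal events (`dv` codes 00/11) flag local
extrema; the beat detector accepts a flagged event if the preceding
monotonic run crossed at least `l_min = 64` levels (a quarter of the
range) within its final 120 ms. Anchoring the count at the reversal
matters: QRS upstrokes often merge with slow baseline drift into one
long monotonic run, so a criterion on the *whole* run's duration would
reject exactly the wide ventricular beats it should catch, while a
criterion on the last 120 ms isolates steepness — and only the QRS
traverses a quarter of the range that fast (T waves manage about a
sixth).

**Algorithm 4 — Pan–Tompkins style.** Preprocessing: order-2 Butterworth
band-pass 5–15 Hz (zero-phase), five-point derivative, squaring, 150 ms
moving-window integration. Decision: the first candidate peak above the
threshold T1 = NPK + 0.25 (SPK − NPK) is the R-peak; sub-threshold
candidates update the noise estimate NPK (0.125/0.875 weights, as for
SPK); a searchback with half threshold fires when no beat appears within
1.66 × the average of the last 8 RR intervals; the threshold halves when
an RR falls outside 92–116% of the running average; the parallel second
threshold on the band-passed signal is not applied. Candidate peaks are
strict local maxima that are also dominant over ± one refractory span:
under measurement noise every ripple is a strict local maximum, NPK is
dragged toward zero by the ripples, and a literal first-local-max rule
then fires on the P-wave shoulder of the integrated feature ~80 ms
early; dominance filtering is the standard peak-candidate rule in
implementations of this detector.

## Synthetic data: what it does and does not emulate

`generate_ecg()` builds each beat from smooth Gaussian bumps (P, QRS,
T) at RR-jittered positions (60 bpm nominal, 5% uniform jitter), plus
sinusoidal baseline wander (0.05 mV at 0.3 Hz) and a white measurement
floor (0.005 mV) — values in the range a scientist would call typical
for a clean clinical recording. Morphology drives the template: V-type
beats are wide (σ = 24 ms), large, P-wave-free with inverted T; paced
beats carry a narrow stimulus spike before a wide complex; L/R are
widened/asymmetric variants; A is a normal-shaped early beat. The R
apex sample is known analytically and becomes the ground-truth
annotation, so there is no annotation-placement ambiguity. Identical
seeds give bitwise-identical records.

`generate_muscle_noise()` is band-limited Gaussian noise, 20–120 Hz,
normalized to unit difference power. The band overlaps QRS spectral
content, which is the property that makes muscular artifact hard for
QRS detectors; it does not reproduce the spectrum, amplitude
modulation, or nonstationarity of a real muscle-artifact recording.

Consequences for interpretation: passing the clean-fixture checks
(every detector reaching TP/TB = 100% at DTT = 17 samples, monotone
accuracy in DTT, exact SNR round trips) demonstrates that the harness,
matcher and detectors behave as designed; it does **not** predict
absolute accuracy on real arrhythmia recordings, where annotation
noise, nonstationary artifact, and morphology variants absent from the
templates all lower the numbers. The benchmark fixture used by the test
suite is three 30 s records at 360 Hz (about 90 beats) spanning all six
classes, times four noise conditions — sizes chosen so a full
4 × 5 × 4 × 6 sweep stays comfortably interactive.

## Numerical conventions and degenerate inputs

* Sample indices are 0-based everywhere (annotations, detections, event
  streams); `fs` converts to time.
* Detector argmax ties break toward the earlier sample (`which.max`).
* WFDB I/O: formats 212 and 16 are read, 16 (and 212, mainly for
  testing the reader) written; amplitudes are quantized by the record's
  gain, so write/read round trips are exact to one ADC step. Beat
  annotations round trip through the MIT `.atr` encoding including the
  SKIP long-interval pseudo-annotation; non-beat annotations are
  discarded on read because only annotated R-peaks enter TB.
* Constant signals produce an empty LC-ADC event stream (not an error);
  all-zero signals produce no detections in any detector.
* Zero denominators in metrics yield `NA`, never an exception; strata
  with TB = 0 are dropped from aggregation, and `aggregate_tp_tb()`
  refuses grids with missing cells, listing them.
* Config for the command-line wrapper is plain flags; results are CSV.
  The run is deterministic given its inputs — reruns produce
  byte-identical tables (asserted in the tests).

## Known limitations

* The two SNR conventions cannot both be physically meaningful; the
  package implements both and takes no position.
* Detector parameter defaults that their original descriptions leave
  unstated (Algorithm 1's window and decay constant, Algorithm 2's
  initialization and threshold fraction, Algorithm 3's beat criterion,
  Algorithm 4's adaptation constants) are this package's documented
  choices; with other choices the absolute TP/TB values will differ,
  which is an inherent property of benchmarking under-specified
  detectors rather than a defect of the harness.
* The harness evaluates single-channel records only and performs no
  resampling; inputs must share one sampling frequency.
* Computational-cost profiling of the detectors is out of scope.
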