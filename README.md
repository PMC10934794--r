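# qrsbench

Multidimensional benchmarking of ECG QRS (R-peak) detectors in R.

Most QRS-detector papers report sensitivity and positive predictivity at
a single, often unstated, matching tolerance. Those numbers hide how
precisely a detector places its marks in time, how the placement
degrades under muscular noise, and which beat morphologies it
struggles with. `qrsbench` is for signal-processing researchers and
device engineers who need to compare detectors along all three axes at
once before committing one to an HRV pipeline, a wearable, or a
clinical analysis chain.

## What it computes

For a set of annotated records, four built-in detectors (or your own
detections) are scored by tolerance-aware matching:

* **TP / FN / FP** — a maximum-cardinality one-to-one pairing between
  detections and reference annotations under
  |detection − annotation| ≤ DTT (the *detection temporal tolerance*),
  swept over a grid of tolerances (default 3, 17, 31, 45, 59 samples =
  8.33 … 163.89 ms at 360 Hz). Shrinking the tolerance converts each
  lost TP into an FN + FP pair.
* **Metrics** — Se = TP/(TP+FN), +P = TP/(TP+FP),
  F1 = 2·PPV·Se/(Se+PPV), DER = (FN+FP)/TB, and the headline
  **TP/TB** ratio, stratified by QRS morphology
  (N, L, R, V, P, A) and by added-noise level.
* **Noise stress** — muscular-artifact noise mixed into each record at
  target SNRs (default 15, 7, 3 dB) using first-difference power
  P = Σ(xᵢ₊₁−xᵢ)²/(N−1) and a scaling factor k applied as
  ECG_test = ECG + k·noise. Both the literal printed SNR convention and
  a power-consistent one are implemented.

The four detectors: (1) a differentiate/moving-average/square feature
with a three-state exponentially decaying threshold; (2) dual
moving-average high-pass paths with an adaptive trigger threshold and a
200 ms search window; (3) a level-crossing ADC simulation with
asymmetric hysteresis plus peak and beat detectors; (4) a
Pan–Tompkins-style detector (Butterworth band-pass, derivative,
squaring, moving-window integration, adaptive thresholds with
searchback). All are parameterized via `algN_params()` constructors.

WFDB records (formats 212 and 16) and MIT-format `.atr` beat
annotations are read and written natively, so the same pipeline runs on
MIT-BIH Arrhythmia Database files; a synthetic generator
(`generate_ecg()`, `generate_muscle_noise()`,
`make_benchmark_fixture()`) provides records with exact ground truth so
everything is testable without any download.

## Worked example

```r
library(qrsbench)
library(dplyr)

out <- generate_ecg(synth_spec(duration_s = 30,
                               morphology = c("N", "N", "V", "N", "A"),
                               seed = 42))
rec <- out$record
out$record
#> <ecg_record 'synth-42'>  10800 samples @ 360 Hz (30.00 s), channel 0, mV

det <- detect_qrs(rec, algorithm = 2)
m <- match_detections(det, out$truth, tolerance_samples = 17L)
m
#> <qrs_match>  DTT = 17 samples: TP 29, FN 0, FP 0 (of 29 annotations, 29 detections)
glance(m)
#> # A tibble: 1 × 9
#>   tolerance_samples    tp    fn    fp    se   ppv    f1   der tp_tb
#>               <int> <int> <int> <int> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1                17    29     0     0   100   100   100     0   100
```

At 17 samples (47 ms) of tolerance, the dual moving-average detector
pairs every one of the 29 annotated beats with a detection and emits
nothing spurious. Sweeping tolerance and noise shows where detectors
differ:

```r
noise <- generate_muscle_noise(duration_s = 30, seed = 43)
sw <- run_sweep(list(rec), list(`synth-42` = out$truth), noise = noise,
                algorithms = c(2, 4), dtt_grid = c(3L, 17L, 59L),
                snr_targets = c(15, 3), mode = "power-consistent")
sw$summary_by_dtt
#> # A tibble: 6 × 5
#>   algorithm dtt_samples  mean   std n_values
#>       <int>       <int> <dbl> <dbl>    <int>
#> 1         2           3 100     0          9
#> 2         2          17 100     0          9
#> 3         2          59 100     0          9
#> 4         4           3  66.7  47.1        9
#> 5         4          17 100     0          9
#> 6         4          59 100     0          9
```

Each row averages the pooled TP/TB over the morphology × noise strata
present (here 9 values). Algorithm 2 keeps 100% down to a 3-sample
(8.3 ms) tolerance on this record; the Pan–Tompkins-style detector
loses a third of its strata at 3 samples — its integrated feature peaks
slightly away from the R apex — and recovers fully by 17 samples.
`autoplot(sw$grid)` draws the full DTT sweep faceted by morphology and
algorithm, and `per_record_report()` reproduces the per-record TP
tables with noise-versus-baseline deltas.

A command-line wrapper for the `synth`, `detect`, `evaluate`, `mix` and
`sweep` verbs is installed at `inst/cli/qrsbench.R`.

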