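# metsig

Detection of the mesenchymal-to-epithelial transition (MET) of invasive
cancer cells from their cell-surface undulation spectra.

## The problem

During metastasis, invasive (mesenchymal-like) tumor cells revert to an
epithelial-like state — the mesenchymal-to-epithelial transition — before
they can seed secondary sites. Conventional MET detection relies on
molecular markers such as vimentin and needs large cell numbers. A
mechanical alternative: park an AFM cantilever (spring constant
k = 0.01 N/m) on the cell body and record the slow height undulations of
the membrane for hours. After MET, the one-sided power spectral density
S(f) of the detrended height signal develops **two distinct peaks in the
0.001–0.007 Hz band** (periods of roughly 2–17 minutes) that are absent in
both the epithelial and the mesenchymal state, and the **positions
(f₁, f₂) of those peaks predict the cell's vimentin percent change**.

`metsig` is for biophysicists and methods developers who want this
pipeline as reusable, testable code. Since no undulation recordings are
publicly deposited, the package ships a seeded generator whose traces are

&nbsp;&nbsp;h(t) = drift·t + ε₁/f(t) + Σₖ Aₖ sin(2π fₖ t + φₖ),

with a 1/f^α coloured-noise background of known RMS and, for post-MET
cells only, two sinusoidal components with in-band frequencies. Every
synthetic cell carries its ground truth (state, f₁, f₂, vimentin change),
so parameter recovery is the verification surface for the whole chain:

1. **signal handling** — trace I/O, deflection→force conversion
   (F = k·d), polynomial detrending, segmentation into overlapping 2-h
   windows;
2. **spectral stage** — Welch PSD (Hann taper, 50% overlap, resolution
   ≈ 2.8×10⁻⁴ Hz), running-median noise floor, prominence-ratio peak
   detection, and the two-peak MET call;
3. **regression stage** — a single-layer gated recurrent (LSTM-style)
   cell with analytic backpropagation-through-time, mapping the ordered
   per-window peak features to vimentin percent change, evaluated by the
   squared Pearson correlation r².

## Worked example

```r
library(metsig)

cfg   <- simulation_config("POST_MET", duration = 21600, seed = 404)
truth <- ground_truth("POST_MET", peak_frequencies = c(0.002, 0.005),
                      config = cfg)
trace <- simulate_trace(cfg, truth)
trace
#> <undulation_trace> cell 'cell': 21600 samples @ 1 s (6 h), RMS 19.6 nm

analysis <- analyze_trace(trace)   # detrend -> windows -> PSD -> peaks
analysis
#> <trace_analysis> cell 'cell': 5 window(s), consensus MET-positive
#>  window_index start_s n_peaks    f1_hz    f2_hz met_positive
#>             1       0       2 0.002011 0.005002         TRUE
#>             2    3600       2 0.001973 0.005014         TRUE
#>             3    7200       2 0.002015 0.005011         TRUE
#>             4   10800       2 0.002015 0.005006         TRUE
#>             5   14400       2 0.002013 0.004988         TRUE

band_period_minutes(analysis$windows$f1_hz[1])
#> [1] 8.286913
```

Both injected oscillations (0.002 and 0.005 Hz) are recovered in every
2-h window to within a fraction of the spectral resolution, the cell is
called MET-positive by the ≥2-peak rule, and the lower peak corresponds
to an ~8-minute oscillation period. An epithelial trace run through the
same chain yields zero in-band peaks and a negative consensus call.

Training the regressor end to end (simulate → spectra → peaks → features
→ fit → held-out r²) is wrapped in one call:

```r
exp <- met_experiment(seed = 1)   # ~30 s on one CPU
exp
#> Synthetic MET parameter-recovery experiment
#>   1000 training sequences (seed 1)
#>   held-out r-squared, cell-line regime (n = 90): 0.967
#>   held-out r-squared, rCTC regime      (n = 38): 0.850
```

`exp$fit` is an ordinary S3 model object with `print`, `summary`, `coef`,
`predict`, `plot`, `fitted` and `residuals` methods, plus plain-text JSON
checkpoints (`write_checkpoint()` / `read_checkpoint()`).

## Command line

A thin launcher over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "metsig.R", package = "metsig"))')
Rscript $CLI simulate   --n 30 --state POST_MET --seed 1 --out-dir runs/sim
Rscript $CLI detect     --manifest runs/sim/manifest.tsv --out-dir runs/det
Rscript $CLI train-eval --manifest runs/sim/manifest.tsv --out-dir runs/fit
Rscript $CLI full-run   --out-dir runs/full --seed 1
```

Exit codes: 0 success, 1 usage/config error, 2 data error, 3 numerical
failure. Every run writes a `run_info.json` manifest (config, MD5 hash,
seed, package version); reruns with equal manifests produce equal
outputs.

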