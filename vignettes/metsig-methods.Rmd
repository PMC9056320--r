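---
title: "Methods: spectral MET detection and the gated recurrent vimentin regressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral MET detection and the gated recurrent vimentin regressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsig)
```

## The measurement and the signature

A soft AFM cantilever (spring constant 0.01 N/m) resting on a cell body
records the slow height undulation of the membrane over several hours,
sampled here at 1 s intervals. Height in nm is the analysis signal;
`deflection_to_force()` provides the equivalent contact force in nN
(F = k·d), but since force is a constant multiple of height, spectra
differ only by k² and peak *positions* are unchanged — a property the
test suite verifies.

The MET signature is spectral: epithelial-state cells show low-amplitude
broadband fluctuations, mesenchymal-state cells show the same spectral
shape at much larger amplitude (3× RMS by default here), and cells that
have undergone MET additionally carry **two distinct oscillation peaks
between 0.001 and 0.007 Hz** — characteristic periods of roughly 2.4 to
17 minutes (`band_period_minutes()`). A cell is called MET-positive when
at least two significant in-band peaks are present. We use "at least
two" rather than "exactly two" as the conservative reading: the
signature is the *emergence* of oscillatory modes, and a third
significant mode should not undo a positive call. Per recording, the
call is aggregated over analysis windows by majority, with ties counted
positive (a tie means half the windows already show the signature).

## Spectral estimation

`estimate_spectrum()` is a Welch estimator: the (detrended) window is cut
into Hann-tapered sub-segments of half the window length with 50%
overlap — three averaged sub-segments per window — each mean-removed,
periodogram-scaled to a one-sided density in nm²/Hz. For the default 2-h
window this gives a resolution of 1/3600 ≈ 2.8×10⁻⁴ Hz, about 21
frequency bins across the MET band: fine enough to separate peaks
6×10⁻⁴ Hz apart (the detector requires resolution ≤ min_separation/2),
coarse enough that three periodograms are averaged and single noise bins
rarely masquerade as peaks. Averaging more sub-segments would halve the
variance again but push the resolution above the minimum peak
separation; this corner of the design is fixed here and exposed through
`seg_duration`.

Integrated power satisfies Parseval: for white noise the mean integrated
density equals the sample variance to within 5%, and a unit-amplitude
sinusoid integrates to A²/2 = 0.5 nm² (both tested). Energy below the
sub-segment resolution (slow drift) is deliberately excluded by the
per-segment mean removal and the preceding linear detrend
(`detrend_trace(order = 1)`, the pipeline default — order 0 leaves piezo
drift in the lowest bins, order 2 starts to absorb real in-band power at
the lowest frequencies).

## Peak detection

"Distinct peak" is operationalized as a local spectral maximum whose
power is at least `significance` times a robust noise floor — the
running median of the power over 9 bins (`estimate_noise_floor()`),
which tracks smooth 1/f-type backgrounds exactly (the median of a
monotone window is its centre value) while ignoring narrow peaks.
Maxima closer than `min_separation = 6e-4` Hz merge, keeping the
higher-power one, ties broken toward the lower frequency. The DC bin and
the first non-DC bin are excluded to avoid detrending leakage. Peak
frequencies are refined by quadratic interpolation of log-power over the
three bins around each maximum, which locates a Hann-tapered tone to a
small fraction of a bin.

The default `significance = 5` was calibrated on the generator's own
epithelial traces: at a prominence ratio of 3 about one epithelial trace
in seven shows a spurious in-band peak (three Welch averages leave
substantial chi-squared scatter), while at 5 the any-false-peak rate is
1–2 per 100 seeded traces and the two-peak recovery rate on post-MET
traces at default SNR remains 97%. The threshold is a tunable argument
everywhere it appears.

## The synthetic generator

No recordings are deposited with the measurement protocol, so the
generator defines the study conditions and carries hidden ground truth:

* **Background**: Gaussian 1/f^α noise (α = 1 by default), synthesized
  in the frequency domain and scaled to an exact RMS. Long-time membrane
  height fluctuations of adherent cells are empirically 1/f-like; the
  exponent is configurable.
* **Amplitudes**: the protocol reports no nm values, so defaults are
  order-of-magnitude choices exposed in `simulation_config()`:
  epithelial and post-MET background 5 nm RMS, mesenchymal 15 nm
  (the "much larger" mesenchymal amplitude), drift 10 nm/h, oscillation
  amplitudes (6, 4) nm. These give in-band peak-to-floor ratios around
  20, comfortably above the detection threshold yet small enough that
  per-cell amplitude heterogeneity produces occasional detection
  dropout in the noisy regime — the failure mode a real cohort would
  show.
* **Peak positions**: f₁ ~ U(0.0012, 0.0035) Hz, f₂ ~ U(0.0040, 0.0068)
  Hz, rejection-sampled until f₂ − f₁ ≥ 6×10⁻⁴ Hz so every simulated
  pair is resolvable by the default estimator.
* **Labels**: vimentin percent change = −100 + 10000·f₁ + 8000·f₂ +
  N(0, σ). The measurement only asserts that peak positions predict the
  vimentin level, so the simplest identifiable (linear, positive-slope)
  map is used; the coefficients put labels in the −56% to −11% range
  (vimentin falls after MET) with a signal SD of ≈ 9.3%.
* **Cohort regimes**: `CELL_LINE` uses label noise σ = 1.5% and
  lognormal per-cell amplitude heterogeneity with sdlog = log 1.2;
  `RCTC` doubles the label noise and widens the heterogeneity 1.5× —
  the noise ceilings implied by this variance budget are r² ≈ 0.97 and
  ≈ 0.90, the synthetic analog of the reported cell-line vs rCTC
  prediction accuracies. Simulated "lines" differ by deterministic
  background-amplitude multipliers (1.0, 1.2, 1.4).

Everything is a pure function of `(config, seed)`; cohorts derive
per-cell seeds from one master seed.

What the generator does **not** emulate: mechanistic cytoskeleton or
adhesion dynamics, osmotically driven volume oscillations, cantilever
dynamics or AFM feedback, non-stationarity of peak frequencies within a
recording, non-Gaussian noise, or instrument artefacts such as contact
loss. Passing recovery tests therefore demonstrates that the pipeline is
correct and well-calibrated *for signals of this structure*; it cannot
certify performance on real recordings, whose peak shapes and noise may
differ.

## Feature extraction

Each 2-h window maps to a 4-vector: the two peak frequencies
standardized by band midpoint and half-width ((f − 0.004)/0.003, so the
band spans [−1, 1]), the number of significant in-band peaks, and the
log of the integrated in-band power. Absent peaks are coded by a
sentinel of −2, outside the standardized band range; a lone peak above
the band midpoint fills the f₂ slot rather than f₁, so partial
detections stay aligned with the geometry they came from. When no window
is peakless the sentinel never activates and predictions are invariant
to its value (tested).

## The gated recurrent regressor

`met_lstm()` is a single-layer gated memory cell — input, forget and
output gates with logistic activations, a tanh candidate, and a linear
readout of the final hidden state — written from first principles with
analytic backpropagation through time; the gradient check against
central finite differences holds to 10⁻⁵ relative error. Defaults:
16 hidden units, full-batch Adam at learning rate 10⁻², 500 epochs,
80/20 train/validation split, mean-squared-error loss on internally
standardized labels, everything seeded. The parameters with the best
validation loss across epochs are returned, which bounds overfitting
without a separate stopping heuristic. Forget-gate biases initialize at
+1 (memory open), the remaining weights uniform on ±(h+d)^{−1/2}.

Sequences of unequal length are grouped by length and processed as
batched tensor operations, so a 1000-sequence epoch is a handful of
matrix products. Degenerate targets (all labels equal) and non-finite
losses raise classed errors rather than silently fitting noise.

The recorded-accuracy metric is the squared Pearson correlation between
predicted and measured vimentin change (`r_squared()`), reported as a
percentage; it is affine-invariant, so it measures association, not
calibrated agreement — the evaluation TSVs keep the raw (predicted,
true) pairs for calibration checks.

## Problem sizes and numerical choices

The recovery experiment (`met_experiment()`) mirrors the study scale:
1000 training sequences over three simulated lines, 30 held-out cells
per line and 38 held-out rCTC-regime cells, each cell a 6-h trace
analyzed in five overlapping 2-h windows. This runs in about half a
minute on one CPU; unit tests use smaller cohorts (tens of cells,
shorter traces) chosen so each property is still informative — e.g. the
permutation-null check trains twenty small models on shuffled labels and
requires the mean held-out r² to stay below 0.15.

Numerical details worth knowing: the coloured-noise synthesizer scales
each realization to an *exact* sample RMS (so amplitude ratios are
deterministic); Welch uses the periodic Hann window with density
normalization dt/Σw²; runmed end rules keep the floor defined at band
edges; peak interpolation clamps the sub-bin offset to ±0.5 bin and the
refined frequency to the band; Adam uses the standard bias corrections
with ε = 10⁻⁸; checkpoints store weights as full-precision JSON.

## Known limitations

* The spectral stage assumes stationary, uniformly sampled traces;
  gaps or drifting sample clocks are rejected, not repaired.
* The two-peak rule does not model intermediate states; a cell with one
  in-band peak is simply called negative.
* The regressor is trained on cell-line-regime data and applied to the
  rCTC regime; cells whose background amplitude suppresses peak
  detection in several windows are out of the training distribution and
  dominate the residual error there.
* r² on 38 cells has a sampling SD of several points; single-seed
  results near a threshold should be read accordingly.
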