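# Shared fixtures, all generated in code.

# Trace holding a pure sinusoid (plus optional white noise and ramp).
make_sine_trace <- function(freq, amplitude = 1, n = 7200, dt = 1,
                            noise_sd = 0, ramp = 0, seed = NULL) {
  tt <- (seq_len(n) - 1) * dt
  x <- amplitude * sin(2 * pi * freq * tt)
  if (length(freq) > 1) {
    x <- rowSums(vapply(seq_along(freq), function(k) {
      amplitude[min(k, length(amplitude))] * sin(2 * pi * freq[k] * tt)
    }, numeric(n)))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  undulation_trace(tt, x + ramp * tt)
}

# Hand-built spectrum_estimate with an arbitrary power curve, for testing the
# noise-floor and peak logic against analytic references.
make_flat_spectrum <- function(value = 1, n = 200, resolution = 2e-4) {
  structure(
    list(frequencies = (0:n) * resolution,
         power = c(0, rep(value, n)),
         resolution = resolution,
         estimator_params = list(seg_length = NA, taper = "none", n_segments = 1)),
    class = "spectrum_estimate")
}

# Feature sequences with labels linear in the mean of the first feature
# column: a recoverable noiseless relation for regressor tests.
make_linear_cohort <- function(n, Tn = 5, d = 3, seed = 1,
                               beta = c(3, -2), noise_sd = 0) {
  set.seed(seed)
  x <- replicate(n, matrix(rnorm(Tn * d), Tn, d), simplify = FALSE)
  y <- vapply(x, function(m) {
    beta[1] * mean(m[, 1]) + beta[2] * mean(m[, 2])
  }, numeric(1))
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

# Minimal peak_set constructor for classifier tests.
make_peak_set <- function(freqs, band = c(0.001, 0.007)) {
  structure(
    data.frame(frequency = freqs, power = rep(1, length(freqs)),
               prominence_ratio = rep(10, length(freqs))),
    band = band, significance = 5, min_separation = 6e-4, resolution = 1/3600,
    class = c("peak_set", "data.frame"))
}
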