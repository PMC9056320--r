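test_that("a pure sinusoid concentrates its variance at its frequency", {
  sp <- estimate_spectrum(make_sine_trace(0.004, amplitude = 1, n = 7200))
  non_dc <- which(sp$frequencies > 0)
  fmax <- sp$frequencies[non_dc][which.max(sp$power[non_dc])]
  expect_lt(abs(fmax - 0.004), sp$resolution + 1e-12)
  # integrated power equals the sinusoid variance A^2/2
  expect_equal(band_power(sp), 0.5, tolerance = 0.05)
})

test_that("a constant segment has vanishing non-DC power", {
  tr <- undulation_trace(0:7199, rep(5, 7200))
  sp <- estimate_spectrum(tr)
  ref <- band_power(estimate_spectrum(make_sine_trace(0.004, n = 7200)))
  expect_lt(max(sp$power[sp$frequencies > 0]), 1e-12 * ref)
})

test_that("the estimator satisfies Parseval on white noise", {
  # mean integrated power over 200 seeded realizations ~ sigma^2 = 1
  totals <- vapply(1:200, function(s) {
    set.seed(s)
    band_power(estimate_spectrum(undulation_trace(0:1023, rnorm(1024)),
                                 f_lo = 0.002))
  }, numeric(1))
  expect_equal(mean(totals), 1, tolerance = 0.05)
  # and per-realization agreement with the segment variance at 2-h length
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(7200)
    sp <- estimate_spectrum(undulation_trace(0:7199, x))
    expect_equal(band_power(sp), var(x), tolerance = 0.05)
  }
})

test_that("estimator rejects segments too short for the band", {
  expect_error(estimate_spectrum(undulation_trace(0:999, rnorm(1000))),
               "too short")
})

test_that("welch estimate agrees with an independent periodogram oracle", {
  # single non-overlapping segment, boxcar-free comparison via spec.pgram on
  # the identical Hann-tapered data
  set.seed(9)
  x <- rnorm(2048)
  sp <- estimate_spectrum(undulation_trace(0:2047, x), seg_duration = 2048,
                          f_lo = 0.002)
  w <- 0.5 * (1 - cos(2 * pi * (0:2047) / 2048))
  xs <- (x - mean(x)) * w
  ref <- Mod(fft(xs))^2 / sum(w^2) # dt = 1
  k <- 5:500
  expect_equal(sp$power[k], 2 * ref[k], tolerance = 1e-10)
})

test_that("the running-median noise floor is robust and tracks 1/f", {
  flat <- make_flat_spectrum(value = 2, n = 100)
  nf <- estimate_noise_floor(flat, band = c(0.002, 0.015))
  expect_equal(nf$floor, rep(2, nrow(nf)))
  # one spiked bin does not move the floor
  spiked <- flat
  spiked$power[50] <- 1e6
  nf2 <- estimate_noise_floor(spiked, band = c(0.002, 0.015))
  expect_equal(nf2$floor, nf$floor, tolerance = 0.01)
  # 1/f background: floor matches the analytic curve away from edges
  pink <- make_flat_spectrum(n = 200)
  pink$power <- c(0, 1 / pink$frequencies[-1])
  nfp <- estimate_noise_floor(pink, band = c(0.005, 0.03))
  expect_equal(nfp$floor, 1 / nfp$frequency, tolerance = 0.1)
  expect_error(estimate_noise_floor(flat, band = c(0.02, 0.05)), "support")
})

test_that("peak detection localizes injected tones and ignores noise", {
  # two sinusoids + weak noise: exactly two peaks, each within one
  # resolution step of an argmax oracle over the injected neighborhoods
  tr <- make_sine_trace(c(0.002, 0.005), amplitude = c(1, 0.8), n = 7200,
                        noise_sd = 0.1, seed = 21)
  sp <- estimate_spectrum(tr)
  pk <- detect_peaks(sp)
  expect_equal(nrow(pk), 2)
  for (f0 in c(0.002, 0.005)) {
    hood <- which(abs(sp$frequencies - f0) < 3 * sp$resolution)
    oracle <- sp$frequencies[hood][which.max(sp$power[hood])]
    expect_lt(min(abs(pk$frequency - oracle)), sp$resolution + 1e-12)
  }
  expect_true(all(pk$prominence_ratio >= attr(pk, "significance")))

  # noise-only spectrum yields no peaks at default significance
  set.seed(31)
  sp0 <- estimate_spectrum(undulation_trace(0:7199, rnorm(7200)))
  expect_equal(nrow(detect_peaks(sp0)), 0)

  # a single sinusoid yields exactly one peak
  sp1 <- estimate_spectrum(make_sine_trace(0.003, n = 7200, noise_sd = 0.1,
                                           seed = 5))
  expect_equal(nrow(detect_peaks(sp1)), 1)
})

test_that("peak detection validates resolution and band support", {
  sp <- estimate_spectrum(make_sine_trace(0.004, n = 7200))
  expect_error(detect_peaks(sp, min_separation = 1e-4), "resolution")
  expect_error(detect_peaks(sp, band = c(0.001, 10)), "support")
})

test_that("peak positions are invariant to height-to-force conversion", {
  tr <- make_sine_trace(c(0.002, 0.005), amplitude = c(1, 0.8), n = 7200,
                        noise_sd = 0.1, seed = 12)
  force <- undulation_trace(tr$time_s, deflection_to_force(tr$height_nm))
  p1 <- detect_peaks(estimate_spectrum(tr))
  p2 <- detect_peaks(estimate_spectrum(force))
  expect_equal(p1$frequency, p2$frequency)
  expect_equal(p1$prominence_ratio, p2$prominence_ratio)
})

test_that("the MET call is the two-peak rule and is monotone in added peaks", {
  expect_true(classify_met(make_peak_set(c(0.002, 0.005)))$positive)
  expect_false(classify_met(make_peak_set(numeric(0)))$positive)
  expect_false(classify_met(make_peak_set(0.003))$positive)
  # adding a significant in-band peak never flips positive to negative
  base <- c(0.002, 0.005)
  expect_true(classify_met(make_peak_set(c(base, 0.0035)))$positive)
  call <- classify_met(make_peak_set(base))
  expect_equal(call$n_band_peaks, 2)
  expect_equal(call$peak_frequencies, base)
})

test_that("band frequencies convert to periods of a few minutes", {
  expect_equal(band_period_minutes(0.007), 1 / (0.007 * 60))
  expect_equal(band_period_minutes(0.001), 1 / (0.001 * 60))
  expect_equal(band_period_minutes(1 / 600), 10)
  expect_error(band_period_minutes(0), "positive")
  expect_error(band_period_minutes(-1), "positive")
})
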