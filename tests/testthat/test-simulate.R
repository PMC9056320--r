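test_that("all stochastic terms off gives a constant baseline trace", {
  cfg <- simulation_config("EPITHELIAL", duration = 7200,
                           amplitude_scale = 0, drift_scale = 0, seed = 1)
  tr <- simulate_trace(cfg, ground_truth("EPITHELIAL"))
  expect_equal(tr$height_nm, rep(0, 7200))
})

test_that("injected post-MET oscillations dominate the raw periodogram", {
  # independent discrete-Fourier oracle on the generated samples
  cfg <- simulation_config("POST_MET", duration = 14400, drift_scale = 0,
                           amplitude_scale = 1, seed = 11)
  gt <- ground_truth("POST_MET", c(0.002, 0.005), config = cfg)
  tr <- simulate_trace(cfg, gt)
  n <- length(tr$height_nm)
  pgram <- Mod(fft(tr$height_nm - mean(tr$height_nm))[2:(n %/% 2)])^2
  freqs <- (1:(n %/% 2 - 1)) / n
  top2 <- sort(freqs[order(pgram, decreasing = TRUE)[1:2]])
  expect_lt(abs(top2[1] - 0.002), 1 / n + 1e-12)
  expect_lt(abs(top2[2] - 0.005), 1 / n + 1e-12)
})

test_that("mesenchymal traces scale the background RMS by the configured factor", {
  epi <- simulation_config("EPITHELIAL", duration = 7200, amplitude_scale = 5,
                           drift_scale = 0, seed = 3)
  mes <- simulation_config("MESENCHYMAL", duration = 7200, amplitude_scale = 15,
                           drift_scale = 0, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  ratio <- rms(simulate_trace(mes, ground_truth("MESENCHYMAL"))$height_nm) /
    rms(simulate_trace(epi, ground_truth("EPITHELIAL"))$height_nm)
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- simulation_config("POST_MET", duration = 7200, seed = 99)
  gt <- ground_truth("POST_MET", c(0.0025, 0.0055), config = cfg)
  expect_identical(simulate_trace(cfg, gt)$height_nm,
                   simulate_trace(cfg, gt)$height_nm)
})

test_that("state and peak list must be mutually consistent", {
  cfg <- simulation_config("POST_MET", duration = 7200)
  expect_error(ground_truth("POST_MET", 0.002), "exactly 2")
  expect_error(ground_truth("EPITHELIAL", c(0.002, 0.005)), "no peak")
  expect_error(ground_truth("POST_MET", c(0.002, 0.0021), config = cfg),
               "min_peak_separation")
  expect_error(ground_truth("POST_MET", c(0.002, 0.02), config = cfg),
               "inside the band")
  expect_error(simulate_trace(cfg, ground_truth("EPITHELIAL")),
               "does not match")
  expect_error(simulation_config("EPITHELIAL", duration = 1000), "two periods")
})

test_that("vimentin labels follow the linear map with Gaussian noise", {
  cfg <- simulation_config("POST_MET", duration = 7200)
  gt <- ground_truth("POST_MET", c(0.002, 0.005), config = cfg)
  # degenerate map
  lab <- assign_vimentin(gt, list(intercept = -40, slope1 = 0, slope2 = 0,
                                  noise_sd = 0))
  expect_equal(lab$vimentin_change, -40)
  # exact linear value, repeated calls identical
  map <- list(intercept = -100, slope1 = 10000, slope2 = 8000, noise_sd = 0)
  v1 <- assign_vimentin(gt, map)$vimentin_change
  expect_equal(v1, -100 + 10000 * 0.002 + 8000 * 0.005)
  expect_identical(v1, assign_vimentin(gt, map)$vimentin_change)
  # Monte-Carlo: sample mean within 3 * sd/sqrt(n) of the noiseless value
  map$noise_sd <- 5
  draws <- vapply(1:1000, function(i) {
    assign_vimentin(gt, map, seed = i)$vimentin_change
  }, numeric(1))
  expect_lt(abs(mean(draws) - v1), 3 * 5 / sqrt(1000))
  # label undefined off the post-MET state
  expect_error(assign_vimentin(ground_truth("EPITHELIAL"), map), "undefined")
})

test_that("labels increase monotonically in each peak frequency for positive slopes", {
  cfg <- simulation_config("POST_MET", duration = 7200)
  map <- list(intercept = 0, slope1 = 10000, slope2 = 8000, noise_sd = 0)
  lab <- function(f1, f2) {
    assign_vimentin(ground_truth("POST_MET", c(f1, f2), config = cfg),
                    map)$vimentin_change
  }
  f1s <- seq(0.0015, 0.003, length.out = 5)
  expect_true(all(diff(vapply(f1s, lab, numeric(1), f2 = 0.005)) > 0))
  f2s <- seq(0.0045, 0.0065, length.out = 5)
  expect_true(all(diff(vapply(f2s, lab, numeric(1), f1 = 0.002)) > 0))
})

test_that("cohorts have the requested size and are seed-deterministic", {
  cfg <- simulation_config("POST_MET", duration = 7200)
  cl <- simulate_cohort(30, "CELL_LINE", config = cfg, seed = 5)
  expect_length(cl, 30)
  expect_true(all(vapply(cl, function(c) c$truth$state == "POST_MET", logical(1))))
  expect_length(simulate_cohort(38, "RCTC", config = cfg, seed = 5), 38)
  a <- simulate_cohort(5, "CELL_LINE", config = cfg, seed = 8)
  b <- simulate_cohort(5, "CELL_LINE", config = cfg, seed = 8)
  expect_identical(lapply(a, function(c) c$trace$height_nm),
                   lapply(b, function(c) c$trace$height_nm))
  expect_identical(vapply(a, function(c) c$truth$vimentin_change, numeric(1)),
                   vapply(b, function(c) c$truth$vimentin_change, numeric(1)))
  expect_error(simulate_cohort(0, config = cfg), "n must be")
})

test_that("drawn peak pairs respect band membership and separation", {
  cfg <- simulation_config("POST_MET", duration = 14400)
  set.seed(42)
  for (i in 1:200) {
    f <- draw_peak_frequencies(cfg)
    expect_true(f[1] < f[2])
    expect_true(all(f >= cfg$band[1] & f <= cfg$band[2]))
    expect_gte(diff(f), cfg$min_peak_separation)
  }
})
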