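#' Simulation configuration for synthetic undulation traces
#'
#' Defines the generative model for one cell state. Traces are the sum of a
#' deterministic linear drift, a 1/f^alpha coloured-noise background scaled to
#' an exact RMS, and (post-MET only) two sinusoidal oscillation components
#' with frequencies inside the MET band.
#'
#' The default background RMS values encode the observed phenomenology:
#' mesenchymal-state undulations are much larger than epithelial-state ones
#' (15 vs 5 nm RMS here), and neither carries in-band spectral peaks; after
#' MET the background returns to the epithelial scale but two oscillatory
#' components appear between 0.001 and 0.007 Hz.
#'
#' @param state One of `"EPITHELIAL"`, `"MESENCHYMAL"`, `"POST_MET"`.
#' @param sampling_interval Seconds per sample (default 1 s; Nyquist 0.5 Hz,
#'   far above the 0.007 Hz band edge).
#' @param duration Trace length in seconds (default 14400 s = 4 h, the
#'   measurement protocol's hold time).
#' @param amplitude_scale RMS of the coloured-noise background in nm. Default
#'   depends on `state`: 5 (EPITHELIAL, POST_MET) or 15 (MESENCHYMAL).
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha background
#'   (default 1).
#' @param drift_scale Slow baseline drift in nm per hour (default 10).
#' @param band MET analysis band `c(f_lo, f_hi)` in Hz (default 0.001-0.007).
#' @param min_peak_separation Minimum separation between the two injected
#'   oscillation frequencies, Hz.
#' @param oscillation_amplitudes Length-2 amplitudes (nm) of the two post-MET
#'   sinusoids.
#' @param f1_range,f2_range Uniform sampling ranges (Hz) for the lower and
#'   upper oscillation frequency.
#' @param vimentin_map Named list `intercept` (percent), `slope1`, `slope2`
#'   (percent per Hz) and `noise_sd` (percent) defining the linear map from
#'   peak frequencies to vimentin percent change.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(state = c("EPITHELIAL", "MESENCHYMAL", "POST_MET"),
                              sampling_interval = 1,
                              duration = 14400,
                              amplitude_scale = NULL,
                              noise_exponent = 1,
                              drift_scale = 10,
                              band = MET_BAND,
                              min_peak_separation = MIN_PEAK_SEPARATION,
                              oscillation_amplitudes = c(6, 4),
                              f1_range = c(0.0012, 0.0035),
                              f2_range = c(0.0040, 0.0068),
                              vimentin_map = list(intercept = -100,
                                                  slope1 = 10000,
                                                  slope2 = 8000,
                                                  noise_sd = 1.5),
                              seed = NULL) {
  state <- match.arg(state)
  amplitude_scale <- amplitude_scale %||%
    switch(state, EPITHELIAL = 5, POST_MET = 5, MESENCHYMAL = 15)
  check_number(sampling_interval, "sampling_interval", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(amplitude_scale, "amplitude_scale", lower = 0)
  check_number(noise_exponent, "noise_exponent", lower = 0)
  check_number(drift_scale, "drift_scale")
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop_usage("band must be c(f_lo, f_hi) with 0 < f_lo < f_hi")
  }
  nyquist <- 1 / (2 * sampling_interval)
  if (band[2] >= nyquist) stop_usage("band upper edge must be below Nyquist")
  if (duration < 2 / band[1]) {
    stop_usage("duration too short: at least two periods of the slowest ",
               "band frequency must fit (duration >= 2/f_lo)")
  }
  if (min_peak_separation <= 1 / duration) {
    stop_usage("min_peak_separation must exceed the frequency resolution 1/duration")
  }
  if (length(oscillation_amplitudes) != 2L || any(oscillation_amplitudes < 0)) {
    stop_usage("oscillation_amplitudes must be two non-negative numbers")
  }
  needed <- c("intercept", "slope1", "slope2", "noise_sd")
  if (!all(needed %in% names(vimentin_map))) {
    stop_usage("vimentin_map needs fields: ", paste(needed, collapse = ", "))
  }
  if (vimentin_map$noise_sd < 0) stop_usage("vimentin_map$noise_sd must be >= 0")
  structure(
    list(state = state, sampling_interval = sampling_interval,
         duration = duration, amplitude_scale = amplitude_scale,
         noise_exponent = noise_exponent, drift_scale = drift_scale,
         band = band, min_peak_separation = min_peak_separation,
         oscillation_amplitudes = oscillation_amplitudes,
         f1_range = f1_range, f2_range = f2_range,
         vimentin_map = vimentin_map, seed = seed),
    class = "simulation_config"
  )
}

#' Ground truth for one simulated cell
#'
#' @param state Cell state; `"POST_MET"` requires exactly two in-band peak
#'   frequencies, the other states require none.
#' @param peak_frequencies Numeric vector of injected oscillation frequencies
#'   (Hz); empty unless post-MET.
#' @param vimentin_change Vimentin percent change label (may be `NA` until
#'   assigned).
#' @param cell_id Identifier.
#' @param cohort `"CELL_LINE"` or `"RCTC"`.
#' @param config The [simulation_config()] the truth must be consistent with.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(state, peak_frequencies = numeric(0),
                         vimentin_change = NA_real_, cell_id = "cell",
                         cohort = c("CELL_LINE", "RCTC"),
                         config = NULL) {
  cohort <- match.arg(cohort)
  if (!state %in% c("EPITHELIAL", "MESENCHYMAL", "POST_MET")) {
    stop_usage("unknown state: ", state)
  }
  if (state == "POST_MET") {
    if (length(peak_frequencies) != 2L) {
      stop_usage("POST_MET truth requires exactly 2 peak frequencies")
    }
    peak_frequencies <- sort(peak_frequencies)
    if (!is.null(config)) {
      if (any(peak_frequencies < config$band[1] | peak_frequencies > config$band[2])) {
        stop_usage("peak frequencies must lie inside the band")
      }
      if (diff(peak_frequencies) < config$min_peak_separation) {
        stop_usage("peak frequencies closer than min_peak_separation")
      }
    }
  } else if (length(peak_frequencies) != 0L) {
    stop_usage(state, " truth must carry no peak frequencies")
  }
  structure(
    list(state = state, peak_frequencies = peak_frequencies,
         vimentin_change = vimentin_change, cell_id = as.character(cell_id),
         cohort = cohort),
    class = "ground_truth"
  )
}

#' Draw a consistent pair of post-MET oscillation frequencies
#'
#' Samples f1 and f2 uniformly from `config$f1_range` and `config$f2_range`,
#' rejecting pairs closer than `config$min_peak_separation`.
#'
#' @param config A [simulation_config()].
#' @return Sorted length-2 numeric vector of frequencies in Hz.
#' @export
draw_peak_frequencies <- function(config) {
  for (i in 1:1000) {
    f1 <- runif(1, config$f1_range[1], config$f1_range[2])
    f2 <- runif(1, config$f2_range[1], config$f2_range[2])
    if (f2 - f1 >= config$min_peak_separation) return(c(f1, f2))
  }
  stop_numerical("could not draw separated peak frequencies; ",
                 "check f1_range/f2_range vs min_peak_separation")
}

# 1/f^alpha Gaussian noise of length n, scaled to exact sample RMS `rms`.
# Built in the frequency domain: independent complex Gaussians with variance
# proportional to f^-alpha, Hermitian-symmetrised, inverse FFT.
colored_noise <- function(n, dt, alpha, rms) {
  if (rms <= 0) return(numeric(n))
  nf <- n %/% 2
  f <- seq_len(nf) / (n * dt)
  S <- f^(-alpha)
  even <- n %% 2 == 0
  Z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * sqrt(S / 2)
  if (even) Z[nf] <- rnorm(1) * sqrt(S[nf]) # Nyquist bin is real
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- Z
  idx <- if (even) 2:nf else 2:(nf + 1)
  spec[n + 2 - idx] <- Conj(spec[idx])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

#' Simulate one undulation trace
#'
#' Generates drift + 1/f^alpha coloured noise (+ two sinusoids for post-MET
#' cells, with phases drawn from the seeded generator). Identical
#' `(config, truth, seed)` give a bit-identical trace.
#'
#' @param config A [simulation_config()].
#' @param truth A [ground_truth()] consistent with `config$state`.
#' @return An [undulation_trace()].
#' @examples
#' cfg <- simulation_config("POST_MET", duration = 7200, seed = 1)
#' tr <- simulate_trace(cfg, ground_truth("POST_MET", c(0.002, 0.005),
#'                                        config = cfg))
#' @export
simulate_trace <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$state != config$state) {
    stop_usage("truth state (", truth$state, ") does not match config state (",
               config$state, ")")
  }
  if (config$state == "POST_MET" && length(truth$peak_frequencies) != 2L) {
    stop_usage("POST_MET simulation requires two peak frequencies in truth")
  }
  n <- as.integer(round(config$duration / config$sampling_interval))
  dt <- config$sampling_interval
  tt <- (seq_len(n) - 1) * dt
  with_seed(config$seed, {
    x <- config$drift_scale * tt / 3600 +
      colored_noise(n, dt, config$noise_exponent, config$amplitude_scale)
    if (config$state == "POST_MET") {
      for (k in 1:2) {
        phi <- runif(1, 0, 2 * pi)
        x <- x + config$oscillation_amplitudes[k] *
          sin(2 * pi * truth$peak_frequencies[k] * tt + phi)
      }
    }
    undulation_trace(tt, x, cell_id = truth$cell_id,
                     annotations = list(state = truth$state,
                                        cohort = truth$cohort))
  })
}

#' Assign a vimentin percent-change label to a post-MET cell
#'
#' The label is linear in the two oscillation frequencies plus Gaussian noise:
#' `intercept + slope1 * f1 + slope2 * f2 + N(0, noise_sd)`. Only post-MET
#' cells carry a label (the marker change is defined relative to the
#' transition).
#'
#' @param truth A POST_MET [ground_truth()].
#' @param map Vimentin map coefficients (see [simulation_config()]).
#' @param seed Optional seed for the noise draw.
#' @return The updated [ground_truth()] with `vimentin_change` set.
#' @export
assign_vimentin <- function(truth, map = simulation_config("POST_MET")$vimentin_map,
                            seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$state != "POST_MET") {
    stop_data("vimentin label undefined for state ", truth$state)
  }
  f <- truth$peak_frequencies
  value <- map$intercept + map$slope1 * f[1] + map$slope2 * f[2]
  if (map$noise_sd > 0) {
    value <- value + with_seed(seed, rnorm(1, 0, map$noise_sd))
  }
  truth$vimentin_change <- value
  truth
}

#' Simulate a cohort of cells
#'
#' Generates `n` independent cells under a common configuration template.
#' The `"RCTC"` regime models the noisier repopulated-CTC population: the
#' vimentin label noise is doubled and the per-cell background-amplitude
#' heterogeneity is 1.5x wider than in the `"CELL_LINE"` regime
#' (lognormal multipliers with sdlog `log(1.2)` for cell lines and
#' `1.5 * log(1.2)` for rCTCs).
#'
#' @param n Number of cells (>= 1).
#' @param regime `"CELL_LINE"` or `"RCTC"`.
#' @param config A [simulation_config()] template (its `seed` is ignored;
#'   per-cell seeds are derived from `seed`).
#' @param seed Integer seed making the whole cohort reproducible.
#' @param cell_id_prefix Prefix for generated cell ids.
#' @param amplitude_multiplier Extra deterministic multiplier on the
#'   background RMS (used to differentiate simulated cell lines).
#' @return List of `n` elements, each `list(trace = , truth = )`.
#' @examples
#' coh <- simulate_cohort(3, config = simulation_config("POST_MET",
#'                        duration = 7200), seed = 1)
#' coh[[1]]$truth$peak_frequencies
#' @export
simulate_cohort <- function(n, regime = c("CELL_LINE", "RCTC"),
                            config = simulation_config("POST_MET"),
                            seed = 1L, cell_id_prefix = "cell",
                            amplitude_multiplier = 1) {
  regime <- match.arg(regime)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_usage("n must be >= 1")
  n <- as.integer(n)
  noise_mult <- if (regime == "RCTC") 2 else 1
  het_sdlog <- log(1.2) * (if (regime == "RCTC") 1.5 else 1)
  seeds <- derive_seeds(seed, 3L * n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$vimentin_map$noise_sd <- config$vimentin_map$noise_sd * noise_mult
    het <- with_seed(seeds[3 * i - 2], exp(rnorm(1, 0, het_sdlog)))
    cfg$amplitude_scale <- config$amplitude_scale * amplitude_multiplier * het
    cfg$seed <- seeds[3 * i - 1]
    id <- sprintf("%s_%04d", cell_id_prefix, i)
    if (config$state == "POST_MET") {
      fs <- with_seed(seeds[3 * i - 2], draw_peak_frequencies(cfg))
      truth <- ground_truth("POST_MET", fs, cell_id = id, cohort = regime,
                            config = cfg)
      truth <- assign_vimentin(truth, cfg$vimentin_map, seed = seeds[3 * i])
    } else {
      truth <- ground_truth(config$state, cell_id = id, cohort = regime)
    }
    list(trace = simulate_trace(cfg, truth), truth = truth)
  })
}

#' Write a cohort to disk (trace files + manifest)
#'
#' Traces are written as two-column CSV under `dir/traces/`; the manifest is a
#' TSV `manifest.tsv` with columns `cell_id`, `cohort`, `state`, `f1_hz`,
#' `f2_hz`, `vimentin_change_pct`, `trace_path` (paths relative to `dir`).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(cell) {
    tr <- cell$trace; gt <- cell$truth
    rel <- file.path("traces", paste0(gt$cell_id, ".csv"))
    write_trace(tr, file.path(dir, rel))
    f <- gt$peak_frequencies
    data.frame(cell_id = gt$cell_id, cohort = gt$cohort, state = gt$state,
               f1_hz = if (length(f)) f[1] else NA_real_,
               f2_hz = if (length(f)) f[2] else NA_real_,
               vimentin_change_pct = gt$vimentin_change,
               trace_path = rel, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.tsv` written by [write_cohort()].
#' @return A data frame with one row per cell.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("manifest not found: ", path),
                        class = c("metsig_io_error", "metsig_error")))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}
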