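#' Estimate the oscillation spectrum of a trace segment
#'
#' One-sided power spectral density by Welch's method: the segment is split
#' into Hann-tapered sub-segments of `seg_duration` seconds with 50% overlap,
#' each mean-removed periodogram is density-scaled (nm^2/Hz), and the results
#' are averaged. The default sub-segment is half the input, so a 2-h window
#' yields three averaged sub-segments and a resolution of 1/3600 ~ 2.8e-4 Hz
#' -- fine enough to separate peaks 6e-4 Hz apart.
#'
#' @param segment An [undulation_trace()], typically one 2-h window of a
#'   detrended recording.
#' @param seg_duration Welch sub-segment length in seconds; default half the
#'   segment duration. The spectral resolution is `1/seg_duration`.
#' @param f_lo Lowest analysis frequency the segment must support; the
#'   segment must span at least `2/f_lo` seconds.
#' @return An object of class `spectrum_estimate`: list with `frequencies`
#'   (Hz, 0..Nyquist), `power` (nm^2/Hz, one-sided), `resolution` (Hz) and
#'   `estimator_params`.
#' @examples
#' tr <- undulation_trace(0:7199, sin(2 * pi * 0.004 * (0:7199)))
#' sp <- estimate_spectrum(tr)
#' sp$frequencies[which.max(sp$power)]
#' @export
estimate_spectrum <- function(segment, seg_duration = NULL, f_lo = MET_BAND[1]) {
  stopifnot(inherits(segment, "undulation_trace"))
  dt <- segment$sampling_interval
  x <- segment$height_nm
  n <- length(x)
  if (n * dt < 2 / f_lo) {
    stop_data(sprintf(
      "segment too short (%g s) for the %g Hz band edge: need >= %g s",
      n * dt, f_lo, 2 / f_lo))
  }
  seg_duration <- seg_duration %||% (n * dt / 2)
  L <- as.integer(round(seg_duration / dt))
  if (L < 8L) stop_usage("seg_duration too short")
  if (L > n) stop_data("seg_duration exceeds the segment duration")
  step <- max(1L, L %/% 2L)
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) # periodic Hann
  U <- sum(w^2)
  nf <- L %/% 2L
  P <- numeric(nf + 1L)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]
    xs <- xs - mean(xs)
    X <- stats::fft(xs * w)[1:(nf + 1L)]
    P <- P + dt * Mod(X)^2 / U
  }
  P <- P / length(starts)
  # one-sided: double everything except DC and (for even L) Nyquist
  last_double <- if (L %% 2L == 0L) nf else nf + 1L
  if (last_double >= 2L) P[2:last_double] <- 2 * P[2:last_double]
  structure(
    list(frequencies = (0:nf) / (L * dt),
         power = P,
         resolution = 1 / (L * dt),
         estimator_params = list(seg_length = L, taper = "hann",
                                 n_segments = length(starts),
                                 sampling_interval = dt)),
    class = "spectrum_estimate"
  )
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectrum_estimate> %d bins to %.4g Hz, resolution %.3g Hz (%d x %d-sample Hann segments)\n",
    length(x$frequencies), max(x$frequencies), x$resolution,
    x$estimator_params$n_segments, x$estimator_params$seg_length))
  invisible(x)
}

#' @export
plot.spectrum_estimate <- function(x, band = MET_BAND, ...) {
  keep <- x$frequencies > 0
  plot(x$frequencies[keep], x$power[keep], type = "l", log = "xy",
       xlab = "frequency (Hz)", ylab = "power (nm²/Hz)",
       main = "Oscillation spectrum", ...)
  abline(v = band, lty = 3, col = "grey40")
  invisible(x)
}

#' Integrated spectral power over a frequency band
#'
#' @param spectrum A `spectrum_estimate`.
#' @param band `c(f_lo, f_hi)` in Hz; `NULL` integrates the whole spectrum.
#' @return Power in nm^2 (density times resolution, summed).
#' @export
band_power <- function(spectrum, band = NULL) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  keep <- if (is.null(band)) rep(TRUE, length(spectrum$frequencies)) else
    spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  sum(spectrum$power[keep]) * spectrum$resolution
}

#' Robust spectral noise floor
#'
#' Estimates the smooth background under a spectrum as a running median of
#' the power over a window of `k` bins (default 9), which is insensitive to
#' narrow peaks, and evaluates it on the requested band's frequency grid.
#'
#' @param spectrum A `spectrum_estimate`.
#' @param band `c(f_lo, f_hi)` in Hz, inside the spectrum's support.
#' @param k Odd running-median window in bins.
#' @return Data frame with columns `frequency` and `floor`.
#' @export
estimate_noise_floor <- function(spectrum, band = MET_BAND, k = 9L) {
  fl <- noise_floor_full(spectrum, k)
  inband <- which(spectrum$frequencies >= band[1] &
                  spectrum$frequencies <= band[2])
  if (!length(inband) || band[2] > max(spectrum$frequencies) ||
      band[1] < spectrum$resolution) {
    stop_data("band lies outside the spectrum support")
  }
  data.frame(frequency = spectrum$frequencies[inband], floor = fl[inband])
}

# running-median floor over all positive-frequency bins, aligned to the full
# frequency grid (NA at DC)
noise_floor_full <- function(spectrum, k = 9L) {
  pos <- which(spectrum$frequencies > 0)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop_usage("k must be odd")
  k <- min(k, if (length(pos) %% 2L == 1L) length(pos) else length(pos) - 1L)
  fl <- rep(NA_real_, length(spectrum$frequencies))
  fl[pos] <- stats::runmed(spectrum$power[pos], k, endrule = "median")
  fl
}

#' Detect significant spectral peaks in the MET band
#'
#' Finds local maxima of the spectrum inside `band` whose power is at least
#' `significance` times the running-median noise floor at that frequency.
#' Maxima closer than `min_separation` are merged, keeping the higher-power
#' one (ties broken toward the lower frequency). The DC bin and the first
#' non-DC bin are excluded to avoid detrending leakage. Peak frequencies are
#' refined by quadratic interpolation of log-power over the three bins around
#' each maximum.
#'
#' @param spectrum A `spectrum_estimate`.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param significance Required ratio of peak power to the local noise floor.
#' @param min_separation Minimum frequency separation between retained peaks
#'   (Hz); the spectrum resolution must be at most `min_separation/2`.
#' @param interpolate Refine peak frequencies by local quadratic
#'   interpolation (default `TRUE`).
#' @return An object of class `peak_set`: a data frame with columns
#'   `frequency`, `power`, `prominence_ratio`, ascending in frequency, with
#'   attributes `band`, `significance`, `min_separation` and `resolution`.
#' @export
detect_peaks <- function(spectrum, band = MET_BAND,
                         significance = PEAK_SIGNIFICANCE,
                         min_separation = MIN_PEAK_SEPARATION,
                         interpolate = TRUE) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  check_number(significance, "significance", lower = 1)
  if (spectrum$resolution > min_separation / 2) {
    stop_usage("spectrum resolution (", signif(spectrum$resolution, 3),
               " Hz) too coarse for min_separation ", min_separation, " Hz")
  }
  if (band[2] > max(spectrum$frequencies) || band[1] < spectrum$resolution) {
    stop_data("band lies outside the spectrum support")
  }
  fl <- noise_floor_full(spectrum)
  p <- spectrum$power
  f <- spectrum$frequencies
  nb <- length(p)
  cand <- which(f >= band[1] & f <= band[2])
  cand <- cand[cand > 2L & cand < nb] # drop DC + first non-DC bin, keep a right neighbour
  is_max <- vapply(cand, function(i) {
    p[i] > p[i - 1L] && p[i] >= p[i + 1L] && p[i] >= significance * fl[i]
  }, logical(1))
  cand <- cand[is_max]
  out <- data.frame(frequency = numeric(0), power = numeric(0),
                    prominence_ratio = numeric(0))
  if (length(cand)) {
    # greedy merge: accept by descending power (ties: lower frequency first)
    ord <- cand[order(-p[cand], f[cand])]
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep) || all(abs(f[i] - f[keep]) >= min_separation)) {
        keep <- c(keep, i)
      }
    }
    keep <- sort(keep)
    freq <- f[keep]
    if (interpolate) {
      freq <- vapply(seq_along(keep), function(j) {
        i <- keep[j]
        lp <- log(pmax(p[(i - 1L):(i + 1L)], .Machine$double.xmin))
        den <- lp[1] - 2 * lp[2] + lp[3]
        delta <- if (den < 0) 0.5 * (lp[1] - lp[3]) / den else 0
        delta <- max(min(delta, 0.5), -0.5)
        min(max(f[i] + delta * spectrum$resolution, band[1]), band[2])
      }, numeric(1))
    }
    out <- data.frame(frequency = freq, power = p[keep],
                      prominence_ratio = p[keep] / fl[keep])
  }
  structure(out, band = band, significance = significance,
            min_separation = min_separation, resolution = spectrum$resolution,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  band <- attr(x, "band")
  cat(sprintf("<peak_set> %d significant peak(s) in [%g, %g] Hz\n",
              nrow(x), band[1], band[2]))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classify MET status from a peak set
#'
#' The MET signature is the emergence of (at least) two distinct oscillation
#' peaks inside the 0.001-0.007 Hz band; epithelial- and mesenchymal-state
#' spectra carry no such peaks.
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @return An object of class `met_call`: list with `positive` (logical),
#'   `n_band_peaks`, `peak_frequencies` and `evidence` (the peak set).
#' @export
classify_met <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  structure(
    list(positive = nrow(peaks) >= 2L,
         n_band_peaks = nrow(peaks),
         peak_frequencies = peaks$frequency,
         evidence = peaks),
    class = "met_call"
  )
}

#' @export
print.met_call <- function(x, ...) {
  cat(sprintf("<met_call> %s (%d in-band peak%s%s)\n",
              if (x$positive) "MET-positive" else "MET-negative",
              x$n_band_peaks, if (x$n_band_peaks == 1L) "" else "s",
              if (x$n_band_peaks)
                paste0(" at ", paste(signif(x$peak_frequencies, 3), collapse = ", "), " Hz")
              else ""))
  invisible(x)
}

#' Convert a peak frequency to its oscillation period in minutes
#'
#' The 0.001-0.007 Hz band corresponds to characteristic periods of roughly
#' 2.4 to 17 minutes.
#'
#' @param frequency Frequency in Hz, positive.
#' @return Period in minutes, `1 / (60 * frequency)`.
#' @examples
#' band_period_minutes(0.007) # ~2.4 min
#' @export
band_period_minutes <- function(frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop_usage("frequency must be positive and finite")
  }
  1 / (60 * frequency)
}
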