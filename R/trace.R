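#' Cell-surface undulation trace
#'
#' Container for a uniformly sampled cell-surface height time series, the raw
#' signal recorded as AFM cantilever deflection while the tip rests on the
#' cell body. Heights are in nanometres, times in seconds.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing with a constant step (relative tolerance `1e-6`).
#' @param height_nm Numeric vector of surface heights in nm, same length as
#'   `time_s`, all finite.
#' @param cell_id Identifier for the recorded cell.
#' @param annotations Named list of free-form metadata.
#'
#' @return An object of class `undulation_trace`: a list with elements
#'   `time_s`, `height_nm`, `sampling_interval` (seconds), `cell_id` and
#'   `annotations`.
#' @examples
#' tr <- undulation_trace(0:99, sin(2 * pi * 0.02 * (0:99)))
#' tr
#' @export
undulation_trace <- function(time_s, height_nm, cell_id = "cell",
                             annotations = list()) {
  if (!is.numeric(time_s) || !is.numeric(height_nm)) {
    stop_usage("time_s and height_nm must be numeric vectors")
  }
  n <- length(time_s)
  if (n < 2L) stop_usage("a trace needs at least 2 samples")
  if (length(height_nm) != n) {
    stop_usage("time_s and height_nm must have equal length")
  }
  if (!all(is.finite(height_nm))) stop_data("all heights must be finite")
  if (!all(is.finite(time_s))) stop_data("all times must be finite")
  steps <- diff(time_s)
  if (any(steps <= 0)) stop_data("times must be strictly increasing")
  dt <- stats::median(steps)
  if (max(abs(steps - dt)) > 1e-6 * dt) {
    stop_data("sampling must be uniform (constant time step)")
  }
  structure(
    list(
      time_s = as.numeric(time_s),
      height_nm = as.numeric(height_nm),
      sampling_interval = dt,
      cell_id = as.character(cell_id),
      annotations = annotations
    ),
    class = "undulation_trace"
  )
}

#' @export
print.undulation_trace <- function(x, ...) {
  dur <- length(x$height_nm) * x$sampling_interval
  cat(sprintf(
    "<undulation_trace> cell '%s': %d samples @ %.6g s (%.3g h), RMS %.3g nm\n",
    x$cell_id, length(x$height_nm), x$sampling_interval, dur / 3600,
    sqrt(mean((x$height_nm - mean(x$height_nm))^2))
  ))
  invisible(x)
}

#' @export
plot.undulation_trace <- function(x, ...) {
  plot(x$time_s / 3600, x$height_nm, type = "l",
       xlab = "time (h)", ylab = "height (nm)",
       main = paste("Surface undulation:", x$cell_id), ...)
  invisible(x)
}

#' @export
as.data.frame.undulation_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, height_nm = x$height_nm)
}

trace_duration <- function(trace) {
  length(trace$height_nm) * trace$sampling_interval
}

#' AFM instrument configuration
#'
#' @param spring_constant Cantilever spring constant in N/m; must be positive.
#'   Defaults to 0.01 N/m, typical of soft silicon-nitride levers used for
#'   live-cell work.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(spring_constant = 0.01) {
  check_number(spring_constant, "spring_constant", lower = 0, strict_lower = TRUE)
  structure(list(spring_constant = spring_constant), class = "instrument_config")
}

#' Convert cantilever deflection to contact force
#'
#' Hooke's law: force = spring constant x deflection. With deflection in nm
#' and stiffness in N/m the product is numerically the force in nN
#' (nm x N/m = 1e-9 N).
#'
#' @param deflection_nm Numeric vector of deflections in nm (finite).
#' @param instrument An [instrument_config()].
#' @return Numeric vector of forces in nN.
#' @examples
#' deflection_to_force(100) # 1 nN at the default 0.01 N/m
#' @export
deflection_to_force <- function(deflection_nm, instrument = instrument_config()) {
  if (!inherits(instrument, "instrument_config")) {
    instrument <- instrument_config(instrument)
  }
  if (!is.numeric(deflection_nm) || !all(is.finite(deflection_nm))) {
    stop_usage("deflection_nm must be finite numeric")
  }
  instrument$spring_constant * deflection_nm
}

#' Read an undulation trace from a delimited text file
#'
#' Expects a two-column headered file (`time_s`, `height_nm`); comma-separated
#' by default, tab-separated for `.tsv` files or with `sep = "\t"`.
#' Non-uniform sampling is an error: no silent resampling is performed.
#'
#' @param path Path to the file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @param cell_id Cell identifier; defaults to the file name without extension.
#' @return An [undulation_trace()].
#' @export
read_trace <- function(path, sep = NULL, cell_id = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("trace file not found: ", path),
                        class = c("metsig_io_error", "metsig_error")))
  }
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.csv(path, sep = sep, colClasses = "numeric"),
    error = function(e) {
      stop(errorCondition(paste0("malformed trace file ", path, ": ",
                                 conditionMessage(e)),
                          class = c("metsig_parse_error", "metsig_error")))
    },
    warning = function(w) {
      stop(errorCondition(paste0("malformed trace file ", path, ": ",
                                 conditionMessage(w)),
                          class = c("metsig_parse_error", "metsig_error")))
    }
  )
  if (ncol(df) < 2L) {
    stop(errorCondition(paste0("expected two columns (time_s, height_nm) in ", path),
                        class = c("metsig_parse_error", "metsig_error")))
  }
  bad <- which(!is.finite(df[[1]]) | !is.finite(df[[2]]))
  if (length(bad)) {
    stop(errorCondition(
      # +1 for the header line
      paste0("non-finite value in ", path, " at line ", bad[1] + 1L),
      class = c("metsig_parse_error", "metsig_error")
    ))
  }
  if (any(diff(df[[1]]) <= 0)) {
    stop(errorCondition(paste0("non-monotone time column in ", path),
                        class = c("metsig_time_error", "metsig_error")))
  }
  cell_id <- cell_id %||% sub("\\.[^.]*$", "", basename(path))
  undulation_trace(df[[1]], df[[2]], cell_id = cell_id)
}

#' Write an undulation trace to CSV
#'
#' Writes `time_s,height_nm` with 17 significant digits so that a
#' write-then-read round trip reproduces the stored values exactly.
#'
#' @param trace An [undulation_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "undulation_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,height_nm", con)
  writeLines(sprintf("%.17g,%.17g", trace$time_s, trace$height_nm), con)
  invisible(path)
}

#' Remove slow drift from a trace
#'
#' Subtracts the least-squares polynomial of the given order from the height
#' signal. Order 1 (the default elsewhere in the pipeline) removes thermal /
#' piezo drift without attenuating oscillations in the 0.001-0.007 Hz band,
#' whose shortest period (~143 s) is far below the trace duration.
#'
#' @param trace An [undulation_trace()].
#' @param order Polynomial order: 0 (mean), 1 (linear) or 2 (quadratic).
#' @return A detrended [undulation_trace()]; the fitted order is recorded in
#'   `annotations$detrend_order`.
#' @export
detrend_trace <- function(trace, order = 1L) {
  stopifnot(inherits(trace, "undulation_trace"))
  if (!order %in% 0:2) stop_usage("detrend order must be 0, 1 or 2")
  # centred/scaled time for conditioning
  tt <- (trace$time_s - mean(trace$time_s)) / (diff(range(trace$time_s)) / 2)
  X <- outer(tt, 0:order, `^`)
  fit <- stats::lm.fit(X, trace$height_nm)
  ann <- trace$annotations
  ann$detrend_order <- as.integer(order)
  undulation_trace(trace$time_s, fit$residuals, cell_id = trace$cell_id,
                   annotations = ann)
}

#' Segment a trace into overlapping analysis windows
#'
#' Cuts the maximal set of full windows of length `window` seconds starting
#' every `stride` seconds, ordered by start time. The count is
#' `floor((duration - window) / stride) + 1`.
#'
#' @param trace An [undulation_trace()].
#' @param window Window length in seconds (defaults to 7200 s = 2 h).
#' @param stride Stride between window starts in seconds (defaults to 3600 s).
#' @return List of [undulation_trace()] windows; each carries
#'   `annotations$window_index` (1-based) and `annotations$window_start_s`.
#' @examples
#' tr <- undulation_trace(0:21599, rnorm(21600))
#' length(segment_windows(tr))            # 5 two-hour windows in 6 h
#' @export
segment_windows <- function(trace, window = 7200, stride = 3600) {
  stopifnot(inherits(trace, "undulation_trace"))
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(stride, "stride", lower = 0, strict_lower = TRUE)
  dt <- trace$sampling_interval
  n <- length(trace$height_nm)
  dur <- n * dt
  if (window > dur) {
    stop_data(sprintf("window (%g s) exceeds trace duration (%g s)", window, dur))
  }
  wlen <- as.integer(round(window / dt))
  step <- as.integer(round(stride / dt))
  if (step < 1L) stop_usage("stride smaller than the sampling interval")
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    ann <- trace$annotations
    ann$window_index <- i
    ann$window_start_s <- trace$time_s[s]
    undulation_trace(trace$time_s[s:(s + wlen - 1L)],
                     trace$height_nm[s:(s + wlen - 1L)],
                     cell_id = trace$cell_id, annotations = ann)
  })
}
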