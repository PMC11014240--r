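#' Uniformly sampled 1-D signal trace
#'
#' The common container for velocity and displacement signals: a numeric
#' vector with a sampling rate, a units tag, per-cycle start indices and a
#' fiducial table (cycle index, marker name, time in seconds from trace
#' start).
#'
#' @param samples numeric vector of signal values.
#' @param fs sampling rate in Hz (> 0).
#' @param units one of `"velocity"` or `"displacement"` optionally suffixed
#'   with the scale, e.g. `"displacement_mm"`.
#' @param cycle_bounds integer vector of 1-based sample indices at which
#'   each cycle starts (sorted, within range).
#' @param fiducials `data.frame` with columns `cycle`, `marker`, `time_s`,
#'   or `NULL`.
#' @param meta optional list of provenance metadata (resolved config,
#'   per-cycle parameters, BBIs).
#' @return an object of class `cwm_trace`.
#' @export
cwm_trace <- function(samples, fs, units = "velocity",
                      cycle_bounds = 1L, fiducials = NULL, meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  cycle_bounds <- as.integer(cycle_bounds)
  if (is.unsorted(cycle_bounds) || any(cycle_bounds < 1L) ||
      any(cycle_bounds > length(samples)))
    stop("cycle_bounds must be sorted indices within the trace")
  if (!is.null(fiducials)) {
    need <- c("cycle", "marker", "time_s")
    if (!all(need %in% names(fiducials)))
      stop("fiducials needs columns: ", paste(need, collapse = ", "))
  }
  structure(
    list(samples = samples, fs = fs, units = units,
         cycle_bounds = cycle_bounds, fiducials = fiducials, meta = meta),
    class = "cwm_trace")
}

#' @export
print.cwm_trace <- function(x, ...) {
  cat(sprintf("<cwm_trace> %d samples @ %g Hz (%.3f s), units = %s, %d cycle(s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$units, length(x$cycle_bounds)))
  invisible(x)
}

#' @export
length.cwm_trace <- function(x) length(x$samples)

#' Time axis of a trace
#' @param trace a `cwm_trace`.
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "cwm_trace"))
  (seq_along(trace$samples) - 1) / trace$fs
}
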