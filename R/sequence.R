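#' @title Long-sequence builder
#' @description Turns per-cycle velocity traces into a long, noisy,
#'   HRV-modulated displacement recording with polynomial drift removed.
#' @name sequence_builder
NULL

#' Simulation run configuration
#'
#' @param seed integer seed (mandatory).
#' @param fs sampling rate in Hz. Default 100.
#' @param n_cycles number of cardiac cycles, or `NULL` if `duration` given.
#' @param duration recording length in seconds (cycles are drawn until the
#'   summed beat intervals cover it; the trace is trimmed to it).
#' @param snr_db additive-white-Gaussian-noise level in dB applied to each
#'   cycle's velocity, or `"none"` to disable. Default 10.
#' @param amplitude_mm peak-to-peak displacement in mm; sampled from
#'   U\[0.5, 1.1\] when `NULL` (the resting-heartbeat chest excursion).
#' @param hrv_sigma_range range the per-run HRV standard deviation is
#'   drawn from (absolute value of a uniform draw). Default
#'   `c(-0.015, 0.015)`.
#' @param detrend_order polynomial order for baseline removal. Default 3.
#' @param sign_convention `"inward_negative"` (default) or
#'   `"inward_positive"`; flips the trace sign.
#' @param retime `"resample"` (deterministic linear resampling, default)
#'   or `"random_edit"` (literal random deletion/duplication of samples).
#' @param timing,velocity,segments named lists overriding individual
#'   parameter ranges of the samplers.
#' @return a `cwm_config` list.
#' @export
cwm_config <- function(seed, fs = 100, n_cycles = NULL, duration = NULL,
                       snr_db = 10, amplitude_mm = NULL,
                       hrv_sigma_range = c(-0.015, 0.015),
                       detrend_order = 3L,
                       sign_convention = c("inward_negative", "inward_positive"),
                       retime = c("resample", "random_edit"),
                       timing = list(), velocity = list(), segments = list()) {
  if (missing(seed)) stop("cwm_config(): seed is mandatory", call. = FALSE)
  # NA seed is allowed at construction (deferred to the CLI); cwm_rng
  # refuses to run with it.
  sign_convention <- match.arg(sign_convention)
  retime <- match.arg(retime)
  if (is.null(n_cycles) && is.null(duration))
    stop("give n_cycles or duration", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!identical(snr_db, "none") && (!is.numeric(snr_db) || !is.finite(snr_db)))
    stop("snr_db must be a finite number or \"none\"", call. = FALSE)
  if (!is.null(amplitude_mm) && amplitude_mm <= 0)
    stop("amplitude_mm must be > 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), fs = fs, n_cycles = n_cycles,
    duration = duration, snr_db = snr_db, amplitude_mm = amplitude_mm,
    hrv_sigma_range = hrv_sigma_range, detrend_order = as.integer(detrend_order),
    sign_convention = sign_convention, retime = retime,
    timing = timing, velocity = velocity, segments = segments),
    class = "cwm_config")
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise variance is set from the signal power so that
#' `10*log10(P_signal / P_noise) = snr_db`.
#'
#' @param trace a [cwm_trace()].
#' @param snr_db signal-to-noise ratio in dB, or `"none"` for identity.
#' @param rng a [cwm_rng()] stream.
#' @return the noisy trace.
#' @export
add_awgn <- function(trace, snr_db, rng) {
  stopifnot(inherits(trace, "cwm_trace"))
  if (identical(snr_db, "none") || is.null(snr_db)) return(trace)
  p_sig <- mean(trace$samples^2)
  if (p_sig <= 0) stop("add_awgn: zero-power input", call. = FALSE)
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  trace$samples <- trace$samples +
    rng_rnorm(rng, length(trace$samples), 0, sd_noise)
  trace
}

#' Sample per-beat heart-rate-variability deviations
#'
#' A per-run HRV standard deviation is taken as the absolute value of a
#' uniform draw on `sigma_range` (default \[-0.015, 0.015\]); per-beat
#' deviations are Normal(0, sigma) clipped to the physiological range
#' \[-0.1, 0.1\]. Beat i then lasts `cycle_len_i * (1 + dev_i)`.
#'
#' @param rng a [cwm_rng()] stream.
#' @param n_cycles number of beats.
#' @param sigma_range range for the per-run sigma draw.
#' @return list with `sigma` (scalar) and `deviations` (length `n_cycles`).
#' @export
sample_hrv_series <- function(rng, n_cycles, sigma_range = c(-0.015, 0.015)) {
  stopifnot(n_cycles >= 1)
  sigma <- abs(rng_runif(rng, 1L, sigma_range[1], sigma_range[2]))
  dev <- if (sigma == 0) rep(0, n_cycles) else
    pmin(pmax(rng_rnorm(rng, n_cycles, 0, sigma), -0.1), 0.1)
  list(sigma = sigma, deviations = dev)
}

#' Retime a cycle trace to a target number of samples
#'
#' Deterministic uniform linear resampling (default), or the literal
#' random deletion/duplication of interior samples (`method =
#' "random_edit"`, needs `rng`). Endpoint values are preserved and
#' fiducial times rescale proportionally.
#'
#' @param trace a [cwm_trace()] (single cycle).
#' @param target_samples desired length (>= 2).
#' @param method `"resample"` or `"random_edit"`.
#' @param rng stream, required for `"random_edit"`.
#' @return the retimed trace.
#' @export
retime_cycle <- function(trace, target_samples,
                         method = c("resample", "random_edit"), rng = NULL) {
  stopifnot(inherits(trace, "cwm_trace"))
  method <- match.arg(method)
  n <- length(trace$samples)
  m <- as.integer(target_samples)
  if (n < 2L) stop("retime_cycle: trace too short")
  if (m < 2L) stop("retime_cycle: target_samples must be >= 2")
  ratio <- m / n
  if (m != n) {
    if (method == "resample") {
      trace$samples <- stats::approx(seq_len(n), trace$samples,
                                     xout = seq(1, n, length.out = m))$y
    } else {
      if (is.null(rng)) stop("random_edit retiming needs an rng")
      if (m < n) {           # delete random interior samples
        drop <- with_rng(rng, sample(2:(n - 1L), n - m))
        trace$samples <- trace$samples[-drop]
      } else if (m > n) {    # duplicate random interior samples
        dup <- with_rng(rng, sample(2:(n - 1L), m - n, replace = TRUE))
        trace$samples <- trace$samples[sort(c(seq_len(n), dup))]
      }
    }
  }
  if (!is.null(trace$fiducials)) trace$fiducials$time_s <-
      trace$fiducials$time_s * ratio
  trace
}

#' Integrate a velocity trace to displacement
#'
#' Cumulative trapezoidal rule at the trace sampling interval;
#' displacement starts at 0.
#'
#' @param trace a velocity [cwm_trace()].
#' @return a displacement trace of equal length.
#' @export
integrate_velocity <- function(trace) {
  stopifnot(inherits(trace, "cwm_trace"))
  if (!startsWith(trace$units, "velocity"))
    stop("integrate_velocity: input units must be velocity", call. = FALSE)
  trace$samples <- .cumtrapz(trace$samples, trace$fs)
  trace$units <- "displacement"
  trace
}

# cumulative trapezoidal integral at sampling rate fs; starts at 0
.cumtrapz <- function(x, fs) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) / fs
}

#' Remove a polynomial baseline trend
#'
#' Fits a least-squares polynomial of the given order to the signal and
#' subtracts it; the default cubic removes the systole/diastole
#' integration imbalance that otherwise tilts long recordings.
#'
#' @param trace a [cwm_trace()] (or plain numeric vector with `fs`).
#' @param order polynomial order (default 3).
#' @param fs sampling rate, only when `trace` is a bare numeric vector.
#' @return detrended trace (same class as the input).
#' @export
detrend_poly <- function(trace, order = 3L, fs = NULL) {
  is_trace <- inherits(trace, "cwm_trace")
  y <- if (is_trace) trace$samples else as.numeric(trace)
  n <- length(y)
  if (n <= order + 1L) stop("detrend_poly: need length > order + 1")
  tt <- if (is_trace) trace_time(trace) else (seq_len(n) - 1) / (fs %||% 1)
  # orthogonal polynomial basis keeps the normal equations well conditioned
  X <- cbind(1, stats::poly(tt, degree = order, raw = FALSE, simple = TRUE))
  fit <- stats::lm.fit(X, y)
  res <- y - as.vector(X %*% fit$coefficients)
  if (is_trace) { trace$samples <- res; trace } else res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a long displacement recording
#'
#' The full pipeline: sample cycle timings, keypoints and velocities;
#' synthesize each cycle's velocity; add white noise; retime each cycle
#' to its HRV-modulated beat interval; concatenate; integrate to
#' displacement; remove the cubic drift; min--max scale to the sampled
#' peak-to-peak amplitude in mm.
#'
#' @param config a [cwm_config()].
#' @return a displacement [cwm_trace()] (units `"displacement_mm"`) with
#'   per-cycle fiducials, the concatenated (unscaled) velocity in
#'   `meta$velocity`, the realized beat intervals in `meta$bbi` and the
#'   resolved configuration in `meta$config`.
#' @export
build_long_sequence <- function(config) {
  stopifnot(inherits(config, "cwm_config"))
  root <- cwm_rng(config$seed)
  r_timing <- rng_child(root, "timing")
  r_vel    <- rng_child(root, "velocity")
  r_noise  <- rng_child(root, "noise")
  r_hrv    <- rng_child(root, "hrv")
  r_amp    <- rng_child(root, "amplitude")

  n_cycles <- config$n_cycles
  if (is.null(n_cycles)) {
    # generous upper bound on beats needed to cover `duration`
    n_cycles <- ceiling(config$duration / 0.58 * 1.1) + 2L
  }
  hrv <- sample_hrv_series(r_hrv, n_cycles, config$hrv_sigma_range)

  cycles <- vector("list", n_cycles)
  bbi <- numeric(n_cycles)
  for (i in seq_len(n_cycles)) {
    cyc <- NULL
    for (try in seq_len(.MAX_REDRAW)) {
      cl <- sample_cycle_length(r_timing, config$timing)
      tm <- sample_phase_durations(r_timing, cl, config$timing)
      sc <- place_keypoints(r_timing, tm, config$timing)
      vk <- sample_velocity_keypoints(r_vel, config$velocity)
      sp <- sample_segment_params(r_vel, tm, config$segments)
      cyc <- tryCatch(
        synthesize_cycle_velocity(tm, sc, vk, sp, config$fs),
        error = function(e) NULL)  # segment under 2 samples: redraw
      if (!is.null(cyc)) break
    }
    if (is.null(cyc))
      stop("build_long_sequence: could not synthesize cycle ", i, call. = FALSE)
    cyc <- add_awgn(cyc, config$snr_db, r_noise)
    bbi[i] <- cyc$meta$timing$cycle_len * (1 + hrv$deviations[i])
    cyc <- retime_cycle(cyc, max(2L, as.integer(round(bbi[i] * config$fs))),
                        method = config$retime, rng = r_hrv)
    cycles[[i]] <- cyc
  }

  lens <- vapply(cycles, length, integer(1))
  starts <- cumsum(c(1L, lens[-n_cycles]))
  v <- unlist(lapply(cycles, `[[`, "samples"), use.names = FALSE)
  fid <- do.call(rbind, lapply(seq_len(n_cycles), function(i) {
    f <- cycles[[i]]$fiducials
    f$cycle <- i
    f$time_s <- f$time_s + (starts[i] - 1L) / config$fs
    f
  }))

  vel_trace <- cwm_trace(v, config$fs, "velocity", cycle_bounds = starts)
  disp <- integrate_velocity(vel_trace)
  disp <- detrend_poly(disp, config$detrend_order)

  amp <- config$amplitude_mm %||% rng_runif(r_amp, 1L, 0.5, 1.1)
  rng_d <- range(disp$samples)
  if (diff(rng_d) > 0)
    disp$samples <- (disp$samples - rng_d[1]) / diff(rng_d) * amp - amp / 2
  if (config$sign_convention == "inward_positive") {
    disp$samples <- -disp$samples
    v <- -v
  }

  if (!is.null(config$duration)) {
    n_keep <- min(length(disp$samples), as.integer(round(config$duration * config$fs)))
    keep_cycles <- starts <= n_keep
    disp$samples <- disp$samples[seq_len(n_keep)]
    v <- v[seq_len(n_keep)]
    disp$cycle_bounds <- starts[keep_cycles]
    fid <- fid[fid$time_s < n_keep / config$fs, , drop = FALSE]
    bbi <- bbi[keep_cycles]
  }
  disp$units <- "displacement_mm"
  disp$fiducials <- fid
  disp$meta <- list(
    config = config, velocity = v, bbi = bbi,
    hrv = hrv, amplitude_mm = amp,
    cycle_params = lapply(cycles, function(cc)
      cc$meta[c("timing", "keypoints", "velocities", "segment_params")]))
  disp
}
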