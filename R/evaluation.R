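#' @title Similarity metrics and spectral tools
#' @description Dynamic time warping and RMSE distances, sliding-window
#'   matching against a reference recording, Hamming-windowed amplitude
#'   spectra, and multi-realization averaged model distances.
#' @name evaluation
NULL

#' Dynamic time warping distance
#'
#' Full dynamic program
#' `D(i,j) = d(A_i, B_j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1))` with
#' absolute-difference local cost and no warping window; returns
#' `D(length(A), length(B))`.
#'
#' @param A,B non-empty numeric vectors.
#' @return non-negative scalar distance (0 for identical sequences).
#' @export
dtw_distance <- function(A, B) {
  A <- as.numeric(A); B <- as.numeric(B)
  if (length(A) == 0L || length(B) == 0L)
    stop("dtw_distance: empty input", call. = FALSE)
  .dtw_dp(A, B)
}

#' Root-mean-squared error
#'
#' @param s,x equal-length numeric vectors.
#' @return `sqrt(mean((s - x)^2))`; 0 iff identical.
#' @export
rmse <- function(s, x) {
  if (length(s) != length(x) || length(s) == 0L)
    stop("rmse: inputs must be non-empty and of equal length", call. = FALSE)
  sqrt(mean((s - x)^2))
}

.minmax01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Best sliding-window distance between a simulation and a reference
#'
#' The first `win_s` seconds of `sim` are compared against every `win_s`
#' window of `ref`, advanced `step` samples at a time; the smallest
#' distance and its offset are returned. Both windows are min--max
#' normalized to \[0, 1\] before comparison unless `normalize = FALSE`.
#'
#' @param sim,ref [cwm_trace()] objects at the same sampling rate.
#' @param win_s window length in seconds (default 5).
#' @param step window step in samples (default 2).
#' @param metric `"dtw"` or `"rmse"`.
#' @param normalize min--max normalize both windows first (default TRUE).
#' @return list with `metric`, `value`, `window_offset` (samples) and
#'   `n_realizations = 1`.
#' @export
sliding_window_min_distance <- function(sim, ref, win_s = 5, step = 2L,
                                        metric = c("dtw", "rmse"),
                                        normalize = TRUE) {
  stopifnot(inherits(sim, "cwm_trace"), inherits(ref, "cwm_trace"))
  metric <- match.arg(metric)
  if (sim$fs != ref$fs)
    stop("sliding_window_min_distance: sampling rates differ", call. = FALSE)
  w <- as.integer(round(win_s * sim$fs))
  if (length(sim$samples) < w || length(ref$samples) < w)
    stop("sliding_window_min_distance: input shorter than the window",
         call. = FALSE)
  s <- sim$samples[seq_len(w)]
  if (normalize) s <- .minmax01(s)
  offsets <- seq(0L, length(ref$samples) - w, by = as.integer(step))
  best <- Inf; best_off <- 0L
  for (off in offsets) {
    r <- ref$samples[(off + 1L):(off + w)]
    if (normalize) r <- .minmax01(r)
    d <- if (metric == "dtw") dtw_distance(s, r) else rmse(s, r)
    if (d < best) { best <- d; best_off <- off }
  }
  list(metric = metric, value = best, window_offset = best_off,
       n_realizations = 1L)
}

#' One-sided amplitude spectrum with a Hamming window
#'
#' Applies a Hamming window, takes the FFT, and returns the one-sided
#' magnitude spectrum with its frequency axis in Hz.
#'
#' @param trace a [cwm_trace()] of length >= 8.
#' @return data.frame with columns `freq_hz`, `magnitude`.
#' @export
amplitude_spectrum <- function(trace) {
  stopifnot(inherits(trace, "cwm_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 8L) stop("amplitude_spectrum: need at least 8 samples", call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- stats::fft(x * w)
  half <- seq_len(floor(n / 2) + 1L)
  data.frame(freq_hz = (half - 1) * trace$fs / n,
             magnitude = Mod(X[half]) / n)
}

#' Average distance of a stochastic generator to a reference
#'
#' Draws `n` seeded realizations from `model_generator`, computes the
#' best sliding-window distance of each against `ref`, and averages.
#'
#' @param model_generator function taking a [cwm_rng()] stream and
#'   returning a [cwm_trace()].
#' @param ref reference [cwm_trace()].
#' @param n number of realizations (default 5).
#' @param metric `"dtw"` or `"rmse"`.
#' @param rng [cwm_rng()] stream seeding the realizations.
#' @param ... passed to [sliding_window_min_distance()].
#' @return list with `metric`, `value` (mean best distance),
#'   `window_offset` (of the last realization) and `n_realizations`.
#' @export
averaged_model_distance <- function(model_generator, ref, n = 5L,
                                    metric = c("dtw", "rmse"), rng, ...) {
  metric <- match.arg(metric)
  stopifnot(n >= 1L)
  vals <- numeric(n); off <- 0L
  for (i in seq_len(n)) {
    tr <- model_generator(rng_child(rng, paste0("realization", i)))
    res <- sliding_window_min_distance(tr, ref, metric = metric, ...)
    vals[i] <- res$value; off <- res$window_offset
  }
  list(metric = metric, value = mean(vals), window_offset = off,
       n_realizations = as.integer(n))
}
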