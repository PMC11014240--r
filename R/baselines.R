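#' @title Published comparison models
#' @description Three literature models of heartbeat chest-wall motion,
#'   provided so simulated-versus-baseline comparisons take one call:
#'   a van der Pol relaxation oscillator, a Gaussian pulse train, and an
#'   improved Gaussian pulse whose acceleration is double-integrated to
#'   displacement.
#' @name baseline_models
NULL

#' Van der Pol oscillator waveform
#'
#' Integrates `x'' - alpha (1 - x^2) x' + omega^2 x = 0` from
#' `(x, x') = (0, 1)` with a fixed-step 4th-order Runge--Kutta scheme at
#' step `1/fs`. With `alpha = 0` this reduces to a harmonic oscillator
#' with closed form `sin(omega t) / omega`.
#'
#' @param duration seconds to integrate.
#' @param fs sampling rate in Hz.
#' @param alpha damping parameter (default 1).
#' @param omega angular frequency in rad/s; defaults to `2*pi/0.82`
#'   (one oscillation per mean cardiac cycle).
#' @param init initial state `c(x, dx)`; default `c(0, 1)`.
#' @return a [cwm_trace()] of `x(t)`.
#' @export
vdp_waveform <- function(duration, fs, alpha = 1, omega = 2 * pi / 0.82,
                         init = c(0, 1)) {
  stopifnot(omega > 0, fs > 0, duration > 0)
  h <- 1 / fs
  n <- as.integer(round(duration * fs))
  deriv <- function(s) c(s[2], alpha * (1 - s[1]^2) * s[2] - omega^2 * s[1])
  out <- numeric(n)
  s <- init
  out[1] <- s[1]
  for (i in seq_len(n - 1L)) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(s))) stop("vdp_waveform: state diverged", call. = FALSE)
    out[i + 1L] <- s[1]
  }
  cwm_trace(out, fs, units = "displacement",
            meta = list(model = "vdp", alpha = alpha, omega = omega))
}

#' Gaussian pulse-train waveform
#'
#' `x(t) = sum_n a * exp(-(t - T_n)^2 / (2 c^2))` with pulse times `Tn`
#' (absolute times, strictly increasing).
#'
#' @param duration seconds of signal.
#' @param fs sampling rate in Hz.
#' @param Tn numeric vector of pulse centres in seconds; defaults to a
#'   train with Gaussian-drawn beat intervals (mean 0.82 s, sd 0.08 s)
#'   when `NULL`, using `rng`.
#' @param a amplitude factor (default 0.2).
#' @param c_width pulse width in seconds (default 0.1).
#' @param rng optional [cwm_rng()] stream for the default pulse times.
#' @return a [cwm_trace()].
#' @export
gaussian_pulse_train <- function(duration, fs, Tn = NULL, a = 0.2,
                                 c_width = 0.1, rng = NULL) {
  stopifnot(c_width > 0, fs > 0, duration > 0)
  if (is.null(Tn)) {
    if (is.null(rng)) stop("gaussian_pulse_train: give Tn or an rng")
    gaps <- numeric(0)
    while (sum(gaps) < duration)
      gaps <- c(gaps, sample_cycle_length(rng))
    Tn <- cumsum(gaps)
  }
  t <- (seq_len(as.integer(round(duration * fs))) - 1L) / fs
  x <- numeric(length(t))
  for (Tk in Tn) x <- x + a * exp(-(t - Tk)^2 / (2 * c_width^2))
  cwm_trace(x, fs, units = "displacement",
            meta = list(model = "pulse_train", a = a, c_width = c_width, Tn = Tn))
}

#' Improved Gaussian pulse displacement
#'
#' Per cycle builds the acceleration
#' `x(t) = g(t) * exp(-(t - b)^2 / c)` with
#' `g(t) = eta * cos(omega t + gamma sin(Omega t))`, `t` running over
#' sample indices (the published constants are index-scale: `b = 50`
#' centres the pulse on sample 50), concatenates cycles and
#' double-integrates to displacement, linearly detrending after each
#' integration pass to suppress the drift the double integral accumulates.
#'
#' @param cycle_lens vector of cycle lengths in seconds; defaults to
#'   `n_cycles` Gaussian draws (mean 0.82 s, sd 0.08 s) using `rng`.
#' @param fs sampling rate in Hz.
#' @param b pulse-centre constant, sample-index scale (default 50).
#' @param c_const Gaussian width constant; a scalar or range the per-cycle
#'   value is drawn from (default `c(0.01, 0.02)`, index scale).
#' @param omega,gamma,Omega,eta modulation constants (defaults 0.2, 0.1,
#'   0.3, 0.5).
#' @param n_cycles number of cycles when `cycle_lens` is `NULL`.
#' @param rng optional [cwm_rng()] stream (cycle lengths, width draw).
#' @return a displacement [cwm_trace()].
#' @export
improved_gaussian_displacement <- function(cycle_lens = NULL, fs = 100,
                                           b = 50, c_const = c(0.01, 0.02),
                                           omega = 0.2, gamma = 0.1,
                                           Omega = 0.3, eta = 0.5,
                                           n_cycles = 10L, rng = NULL) {
  if (any(c_const <= 0)) stop("c_const must be positive", call. = FALSE)
  if (is.null(cycle_lens)) {
    if (is.null(rng)) stop("give cycle_lens or an rng")
    cycle_lens <- vapply(seq_len(n_cycles), function(i)
      sample_cycle_length(rng), numeric(1))
  }
  stopifnot(all(cycle_lens > 0))
  acc <- unlist(lapply(cycle_lens, function(cl) {
    idx <- seq_len(as.integer(round(cl * fs))) - 1L  # sample-index time
    cc <- if (length(c_const) == 2L && !is.null(rng))
      rng_runif(rng, 1L, c_const[1], c_const[2]) else c_const[1]
    eta * cos(omega * idx + gamma * sin(Omega * idx)) * exp(-(idx - b)^2 / cc)
  }), use.names = FALSE)
  bounds <- cumsum(c(1L, as.integer(round(cycle_lens * fs))))
  bounds <- bounds[-length(bounds)]
  # acceleration -> velocity -> displacement, linear detrend per pass
  vel <- detrend_poly(.cumtrapz(acc, fs), order = 1L, fs = fs)
  disp <- detrend_poly(.cumtrapz(vel, fs), order = 1L, fs = fs)
  cwm_trace(disp, fs, units = "displacement", cycle_bounds = bounds,
            meta = list(model = "improved_gauss", b = b, omega = omega,
                        gamma = gamma, Omega = Omega, eta = eta))
}
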