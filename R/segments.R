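#' @title Piecewise velocity segment functions
#' @description One cardiac cycle of chest-wall velocity is assembled from
#'   ten contiguous segments (pb, bc, cj, je, ef, fg, gt, th, hk, fill),
#'   each shaped by a simple analytic function and affinely rescaled onto
#'   its sampled extremal velocities.
#' @name velocity_synthesizer
NULL

.seg_time <- function(L, fs) {
  if (L <= 0) stop("segment length must be > 0", call. = FALSE)
  n <- max(0L, as.integer(round(L * fs)))
  if (n < 2L) stop("segment too short for fs: fewer than 2 samples fit in ",
                   signif(L, 4), " s at ", fs, " Hz", call. = FALSE)
  (seq_len(n) - 1L) / fs
}

#' Affinely rescale a waveform onto a velocity interval
#'
#' Order-preserving map sending the array minimum to `v_min` and maximum
#' to `v_max`. A constant array maps to the interval midpoint.
#'
#' @param samples numeric vector (non-empty).
#' @param v_min,v_max target extremes, `v_max >= v_min`.
#' @return rescaled numeric vector.
#' @export
rescale_to_interval <- function(samples, v_min, v_max) {
  if (length(samples) == 0L) stop("rescale_to_interval: empty input")
  if (v_max < v_min) stop("rescale_to_interval: v_max < v_min")
  lo <- min(samples); hi <- max(samples)
  if (hi - lo < .Machine$double.eps * max(abs(lo), abs(hi), 1))
    return(rep((v_min + v_max) / 2, length(samples)))
  v_min + (samples - lo) * (v_max - v_min) / (hi - lo)
}

#' Sinusoidal shape of the P-to-b (atrial systole) segment
#'
#' `sin(2*pi*t/(alpha*L) + theta)` on `t` in `[0, L)`: a rise then fall
#' covering at most three quarters of a period.
#'
#' @param L segment duration in seconds.
#' @param fs sampling rate in Hz.
#' @param theta initial phase, radians, in `[pi/12, pi/4]`.
#' @param alpha period factor in `[4/3, 2]` (period = `alpha * L`).
#' @return numeric vector of shape values.
#' @export
seg_sinusoid_pb <- function(L, fs, theta, alpha) {
  t <- .seg_time(L, fs)
  sin(2 * pi * t / (alpha * L) + theta)
}

#' Logistic (sigmoid) shape of the bc and fg segments
#'
#' Standard logistic centred at the segment midpoint,
#' `1 / (1 + exp(-k (t - L/2)))`, with the steepness `k` solved from the
#' saturation requirement `1 / (1 + exp(-k L/2)) = saturation` so both
#' endpoints lie in the saturation region (0.9 for bc, 0.99 for fg).
#'
#' @inheritParams seg_sinusoid_pb
#' @param saturation endpoint value in (0.5, 1).
#' @return strictly increasing numeric vector.
#' @export
seg_logistic <- function(L, fs, saturation) {
  if (saturation <= 0.5 || saturation >= 1)
    stop("saturation must be in (0.5, 1)")
  t <- .seg_time(L, fs)
  k <- 2 * log(saturation / (1 - saturation)) / L
  1 / (1 + exp(-k * (t - L / 2)))
}

#' Exponential-decay shape of the cj and ef segments
#'
#' `exp(-k t)` with `k = -log(target)/L` so the value at `t = L` is
#' exactly `target` (0.01 for cj; beta in `[0.001, 0.1]` for ef).
#'
#' @inheritParams seg_sinusoid_pb
#' @param target terminal value in (0, 1).
#' @return strictly decreasing numeric vector starting at 1.
#' @export
seg_exp_decay <- function(L, fs, target) {
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  t <- .seg_time(L, fs)
  exp(log(target) / L * t)
}

#' Rayleigh shape of the Je and filling segments
#'
#' `(t/sigma^2) * exp(-t^2 / (2 sigma^2))`: zero at the origin, unimodal
#' with its maximum at `t = sigma`.
#'
#' @inheritParams seg_sinusoid_pb
#' @param sigma Rayleigh scale in seconds (`L_je` for the Je segment;
#'   `sqrt(sigma2)` with `sigma2` drawn from `[0.3, 0.7] * L_rpf` clipped
#'   to `[0.03, 0.06]` for the filling segment).
#' @return numeric vector of shape values.
#' @export
seg_rayleigh <- function(L, fs, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  t <- .seg_time(L, fs)
  (t / sigma^2) * exp(-t^2 / (2 * sigma^2))
}

#' Cosine shape of the gt segment
#'
#' `cos(2*pi*f_gt*t)` with `f_gt = alpha_gt / L`: a slow decay from 1.
#'
#' @inheritParams seg_sinusoid_pb
#' @param alpha_gt frequency factor in `[1/6, 3/5]`.
#' @return numeric vector starting at 1.
#' @export
seg_cosine_gt <- function(L, fs, alpha_gt) {
  t <- .seg_time(L, fs)
  cos(2 * pi * (alpha_gt / L) * t)
}

#' Phase-shifted sine shape of the th segment
#'
#' `sin(2*pi*t/(r_th*L) + 3*pi/2)`: starts at its minimum (-1) and rises.
#'
#' @inheritParams seg_sinusoid_pb
#' @param r_th period factor in `[3/2, 2]` (period = `r_th * L`).
#' @return numeric vector starting at -1.
#' @export
seg_sine_th <- function(L, fs, r_th) {
  t <- .seg_time(L, fs)
  sin(2 * pi * t / (r_th * L) + 3 * pi / 2)
}

#' Skewed-Gaussian shape of the hk (isovolumetric relaxation) segment
#'
#' `(1/sqrt(2 pi sigma^2)) * exp(-(t-mu)^2/(2 sigma^2)) *
#'  (1 - gamma ((t-mu)/sigma)^3)`; `gamma < 0` skews left, `> 0` right.
#'
#' @inheritParams seg_sinusoid_pb
#' @param mu peak position in seconds (within the IVR span).
#' @param sigma width in seconds, in `[0.01, 0.2]`.
#' @param gamma skewness in `[-0.5, 0.2]`.
#' @return numeric vector of shape values.
#' @export
seg_skew_gauss_hk <- function(L, fs, mu, sigma, gamma) {
  if (sigma <= 0) stop("sigma must be > 0")
  t <- .seg_time(L, fs)
  z <- (t - mu) / sigma
  (1 / sqrt(2 * pi * sigma^2)) * exp(-z^2 / 2) * (1 - gamma * z^3)
}

.segment_param_defaults <- function() list(
  theta_pb   = c(pi / 12, pi / 4),
  alpha_pb   = c(4 / 3, 2),
  sat_bc     = 0.9,
  cj_target  = 0.01,
  beta_ef    = c(0.001, 0.1),
  sat_fg     = 0.99,
  alpha_gt   = c(1 / 6, 3 / 5),
  r_th       = c(3 / 2, 2),
  mu_hk_frac = c(1 / 3, 1),
  sigma_hk   = c(0.01, 0.2),
  gamma_hk   = c(-0.5, 0.2),
  s2_fill_frac = c(0.3, 0.7),
  s2_fill_clip = c(0.03, 0.06)
)

#' Sample the shape parameters of the ten segments
#'
#' @param rng a [cwm_rng()] stream.
#' @param timing a `cwm_cycle_timing` (needed for the IVR-anchored hk peak
#'   and the filling-width fraction of `L_rpf`).
#' @param params optional overrides of the shape-parameter ranges.
#' @return a named list of scalar shape parameters.
#' @export
sample_segment_params <- function(rng, timing, params = list()) {
  stopifnot(inherits(timing, "cwm_cycle_timing"))
  p <- .merge_ranges(.segment_param_defaults(), params)
  s2 <- rng_runif(rng, 1L, p$s2_fill_frac[1], p$s2_fill_frac[2]) * timing$L_rpf
  s2 <- min(max(s2, p$s2_fill_clip[1]), p$s2_fill_clip[2])
  list(
    theta_pb = rng_runif(rng, 1L, p$theta_pb[1], p$theta_pb[2]),
    alpha_pb = rng_runif(rng, 1L, p$alpha_pb[1], p$alpha_pb[2]),
    sat_bc   = p$sat_bc,
    cj_target = p$cj_target,
    beta_ef  = rng_runif(rng, 1L, p$beta_ef[1], p$beta_ef[2]),
    sat_fg   = p$sat_fg,
    alpha_gt = rng_runif(rng, 1L, p$alpha_gt[1], p$alpha_gt[2]),
    r_th     = rng_runif(rng, 1L, p$r_th[1], p$r_th[2]),
    mu_hk    = rng_runif(rng, 1L, p$mu_hk_frac[1], p$mu_hk_frac[2]) * timing$L_ivr,
    sigma_hk = rng_runif(rng, 1L, p$sigma_hk[1], p$sigma_hk[2]),
    gamma_hk = rng_runif(rng, 1L, p$gamma_hk[1], p$gamma_hk[2]),
    sigma_fill = sqrt(s2)
  )
}

#' Synthesize the velocity trace of one cardiac cycle
#'
#' Evaluates the ten segment shapes on the sampled timeline, rescales each
#' onto its velocity interval and concatenates them. Rescale intervals:
#' pb to \[v_b, v_afp\], bc to \[v_b, v_aop\], cj to \[v_j, v_aop\],
#' je to \[v_j, v_e\], ef to \[v_f, v_e\], fg to \[v_f, v_g\],
#' gt to \[v_t, last fg value\] (preserving continuity at g),
#' th to \[v_t, v_h\], hk to \[v_ivrv, v_ivrp\], fill to \[0, v_rpf\].
#' Junction continuity is otherwise not enforced; per-junction jump
#' magnitudes are reported in the trace metadata.
#'
#' @param timing a `cwm_cycle_timing`.
#' @param schedule a `cwm_keypoints` from [place_keypoints()].
#' @param vk a `cwm_velocity_keypoints`.
#' @param seg_params list from [sample_segment_params()].
#' @param fs sampling rate in Hz (>= 50).
#' @return a [cwm_trace()] of `round(cycle_len * fs)` velocity samples
#'   with the keypoints attached as fiducials.
#' @export
synthesize_cycle_velocity <- function(timing, schedule, vk, seg_params, fs) {
  stopifnot(inherits(timing, "cwm_cycle_timing"),
            inherits(schedule, "cwm_keypoints"),
            inherits(vk, "cwm_velocity_keypoints"))
  if (fs < 50) stop("fs must be >= 50 Hz for the shortest segments")
  sc <- schedule; sp <- seg_params
  n_total <- as.integer(round(timing$cycle_len * fs))

  # segment boundaries in samples; last segment absorbs the rounding tail
  bounds_t <- c(0, sc$b, sc$c, sc$J, sc$e, sc$f, sc$g, sc$t, sc$h, sc$k,
                timing$cycle_len)
  idx <- as.integer(round(bounds_t * fs))
  idx[length(idx)] <- n_total
  n_seg <- diff(idx)
  if (any(n_seg < 2L))
    stop("synthesize_cycle_velocity: segment with fewer than 2 samples; ",
         "increase fs", call. = FALSE)
  len <- n_seg / fs  # realized (sample-quantized) segment durations

  shapes <- list(
    pb  = seg_sinusoid_pb(len[1], fs, sp$theta_pb, sp$alpha_pb),
    bc  = seg_logistic(len[2], fs, sp$sat_bc),
    cj  = seg_exp_decay(len[3], fs, sp$cj_target),
    je  = seg_rayleigh(len[4], fs, timing$L_je),
    ef  = seg_exp_decay(len[5], fs, sp$beta_ef),
    fg  = seg_logistic(len[6], fs, sp$sat_fg),
    gt  = seg_cosine_gt(len[7], fs, sp$alpha_gt),
    th  = seg_sine_th(len[8], fs, sp$r_th),
    # hk shape: local time runs from h; the IVR-anchored peak sits at
    # (T_end - h) + mu_hk in segment-local time
    hk  = seg_skew_gauss_hk(len[9], fs,
                            (sc$T_end - sc$h) + sp$mu_hk, sp$sigma_hk,
                            sp$gamma_hk),
    fill = seg_rayleigh(len[10], fs, sp$sigma_fill))

  seg_fg <- rescale_to_interval(shapes$fg, vk$v_f, vk$v_g)
  v <- c(
    rescale_to_interval(shapes$pb, vk$v_b, vk$v_afp),
    rescale_to_interval(shapes$bc, vk$v_b, vk$v_aop),
    rescale_to_interval(shapes$cj, vk$v_j, vk$v_aop),
    rescale_to_interval(shapes$je, vk$v_j, vk$v_e),
    rescale_to_interval(shapes$ef, vk$v_f, vk$v_e),
    seg_fg,
    rescale_to_interval(shapes$gt, vk$v_t, seg_fg[length(seg_fg)]),
    rescale_to_interval(shapes$th, vk$v_t, vk$v_h),
    rescale_to_interval(shapes$hk, vk$v_ivrv, vk$v_ivrp),
    rescale_to_interval(shapes$fill, 0, vk$v_rpf))
  stopifnot(length(v) == n_total)

  seg_names <- c("pb", "bc", "cj", "je", "ef", "fg", "gt", "th", "hk", "fill")
  starts <- idx[-length(idx)] + 1L
  jumps <- abs(v[starts[-1]] - v[starts[-1] - 1L])
  fid <- data.frame(
    cycle = 1L,
    marker = c("P_peak", "b", "c", "S", "J", "e", "f", "g", "t", "h", "k",
               "R", "T_peak", "T_end"),
    time_s = c(sc$P_peak, sc$b, sc$c, sc$S, sc$J, sc$e, sc$f, sc$g, sc$t,
               sc$h, sc$k, sc$R, sc$T_peak, sc$T_end),
    stringsAsFactors = FALSE)
  cwm_trace(v, fs, units = "velocity", cycle_bounds = 1L, fiducials = fid,
            meta = list(timing = timing, keypoints = sc, velocities = vk,
                        segment_params = sp,
                        segment_start_index = stats::setNames(starts, seg_names),
                        junction_jumps = stats::setNames(jumps, seg_names[-1])))
}
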