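#' @title Cardiac-cycle timing sampler
#' @description Draws the duration of a cardiac cycle, splits it into its
#'   physiological phases, places the landmark points of the piecewise
#'   velocity model on the cycle timeline, and samples the extremal
#'   velocities each phase is rescaled onto.
#' @name timing_sampler
#' @details
#' A cycle runs from one P-wave peak to the next. Atrial systole occupies
#' the start of the cycle up to the R instant; systole (isovolumetric
#' contraction, ejection, T-wave) follows; diastole closes the cycle with
#' isovolumetric relaxation, rapid filling and reduced filling, the next
#' atrial systole straddling the boundary. All durations are seconds.
NULL

# Default parameter ranges. Every entry can be overridden through the
# `timing:` / `velocity:` sections of a run configuration.
.timing_defaults <- function() list(
  cycle_len_mean   = 0.82,
  cycle_len_sd     = 0.08,
  cycle_len_range  = c(0.58, 1.07),
  r_sys_dia        = c(0.7, 0.9),
  r_ivc            = c(0.09, 0.13),
  qrs_ivc_factor   = c(1.8, 2.5),
  qrs_max          = 0.120,
  L_sj             = c(0.01, 0.03),
  L_st             = c(0.07, 0.09),
  r_ivr            = c(0.09, 0.13),
  r_asys           = c(0.16, 0.22),
  r_rpf            = c(0.25, 0.40),
  L_je             = c(0.02, 0.03),
  g_frac           = c(0.20, 0.30),
  t_frac           = c(0.40, 0.60),
  h_frac           = c(0.75, 1.00)
)

.velocity_defaults <- function() list(
  v_rpfp       = c(0.02, 0.08),
  v_afp_frac   = c(0.2, 0.5),
  v_b          = c(-0.02, 0.02),
  v_aop        = c(-0.01, 0.02),
  v_rpe        = c(0.04, 0.14),
  v_j_frac     = c(0.1, 0.7),
  v_e_max      = 0.1,
  v_f_frac     = c(0.5, 1.0),
  v_g_max      = 0.01,
  v_t_frac     = c(0.1, 0.5),
  v_h          = c(-0.001, 0.005),
  v_ivrp       = c(0.01, 0.02),
  v_ivrv       = c(-0.01, 0),
  v_rpf        = c(0.02, 0.08)
)

.merge_ranges <- function(defaults, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    # a scalar override of a range pins the draw to that value
    if (length(defaults[[nm]]) == 2L && length(ov) == 1L) ov <- c(ov, ov)
    defaults[[nm]] <- ov
  }
  defaults
}

.MAX_REDRAW <- 1000L

#' Sample one cardiac-cycle duration
#'
#' Draws from a Gaussian with mean 0.82 s and standard deviation 0.08 s,
#' truncated by rejection to the resting-heart-rate window
#' \[0.58, 1.07\] s (56--102 bpm, `floor(60/bpm, 2)` at the fast end).
#'
#' @param rng a [cwm_rng()] stream.
#' @param params optional list of overrides for `cycle_len_mean`,
#'   `cycle_len_sd`, `cycle_len_range`.
#' @return cycle duration in seconds.
#' @export
sample_cycle_length <- function(rng, params = list()) {
  p <- .merge_ranges(.timing_defaults(), params)
  lo <- p$cycle_len_range[1]; hi <- p$cycle_len_range[2]
  for (i in seq_len(.MAX_REDRAW)) {
    x <- rng_rnorm(rng, 1L, p$cycle_len_mean, p$cycle_len_sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("sample_cycle_length: rejection sampling failed after ",
       .MAX_REDRAW, " draws (inconsistent overrides?)", call. = FALSE)
}

#' Sample the phase durations of one cardiac cycle
#'
#' Splits `cycle_len` into systole and diastole via the systolic/diastolic
#' ratio r ~ U\[0.7, 0.9\], then draws each phase duration from its
#' stated range. Redraws (up to a bounded limit) until every derived
#' duration is positive, the QRS complex does not exceed 120 ms and atrial
#' systole exceeds the QRS duration.
#'
#' @inheritParams sample_cycle_length
#' @param cycle_len cycle duration in seconds.
#' @return a `cwm_cycle_timing` list; see Details for fields.
#' @details Fields: `cycle_len`, `r_sys_dia`, `L_sys`, `L_dia`, `L_ivc`,
#'   `L_qrs`, `L_sj`, `L_st`, `L_ivr`, `L_asys`, `L_rpf`, `L_rdf`, `L_pb`,
#'   `L_twave`, `L_je`. Conservation: `L_sys + L_dia == cycle_len` and
#'   `L_ivr + L_rpf + L_rdf + L_asys == L_dia`;
#'   `L_pb = L_asys - (L_qrs - L_ivc)`;
#'   `L_twave = L_sys - L_ivc - L_sj - L_st`.
#' @export
sample_phase_durations <- function(rng, cycle_len, params = list()) {
  p <- .merge_ranges(.timing_defaults(), params)
  if (cycle_len < p$cycle_len_range[1] - 1e-12 ||
      cycle_len > p$cycle_len_range[2] + 1e-12)
    stop("cycle_len outside configured range [",
         p$cycle_len_range[1], ", ", p$cycle_len_range[2], "]", call. = FALSE)

  for (i in seq_len(.MAX_REDRAW)) {
    r     <- rng_runif(rng, 1L, p$r_sys_dia[1], p$r_sys_dia[2])
    L_dia <- cycle_len / (1 + r)
    L_sys <- r * cycle_len / (1 + r)
    r_ivc <- rng_runif(rng, 1L, p$r_ivc[1], p$r_ivc[2])
    L_ivc <- r_ivc * L_sys
    L_qrs <- min(rng_runif(rng, 1L, p$qrs_ivc_factor[1], p$qrs_ivc_factor[2]) * L_ivc,
                 p$qrs_max)
    L_sj  <- rng_runif(rng, 1L, p$L_sj[1], p$L_sj[2])
    L_st  <- rng_runif(rng, 1L, p$L_st[1], p$L_st[2])
    L_ivr <- rng_runif(rng, 1L, p$r_ivr[1], p$r_ivr[2]) * L_dia
    L_asys <- rng_runif(rng, 1L, p$r_asys[1], p$r_asys[2]) * L_dia
    if (L_asys <= L_qrs) next  # atrial systole must exceed the QRS complex
    L_rpf <- rng_runif(rng, 1L, p$r_rpf[1], p$r_rpf[2]) * L_dia
    L_rdf <- L_dia - L_ivr - L_rpf - L_asys
    L_pb  <- L_asys - (L_qrs - L_ivc)
    L_twave <- L_sys - L_ivc - L_sj - L_st
    L_je  <- rng_runif(rng, 1L, p$L_je[1], p$L_je[2])
    if (L_rdf <= 0 || L_pb <= 0 || L_twave <= 0 || L_qrs <= L_ivc) next
    return(structure(list(
      cycle_len = cycle_len, r_sys_dia = r,
      L_sys = L_sys, L_dia = L_dia, L_ivc = L_ivc, L_qrs = L_qrs,
      L_sj = L_sj, L_st = L_st, L_ivr = L_ivr, L_asys = L_asys,
      L_rpf = L_rpf, L_rdf = L_rdf, L_pb = L_pb, L_twave = L_twave,
      L_je = L_je), class = "cwm_cycle_timing"))
  }
  stop("sample_phase_durations: no consistent phase split after ",
       .MAX_REDRAW, " redraws", call. = FALSE)
}

#' Place the landmark points of one cycle on its timeline
#'
#' The P-wave peak defines time 0. Point b (the Q-wave-adjacent velocity
#' minimum) sits at the end of the P--b interval; c is uniform inside the
#' R--S span (where isovolumetric contraction happens); S, J, e and f
#' (T-wave onset) follow from the sampled interval durations; g, t and h
#' sit at uniform fractions of the T-wave; k (the relaxation trough, which
#' can spill into filling) is uniform between mid-IVR and mid-rapid-fill.
#'
#' @inheritParams sample_cycle_length
#' @param timing a `cwm_cycle_timing` from [sample_phase_durations()].
#' @return a `cwm_keypoints` list of times in seconds from cycle start:
#'   `P_peak`, `b`, `c`, `S`, `J`, `e`, `f`, `g`, `t`, `h`, `k`,
#'   `cycle_end`, plus derived fiducials `R`, `T_peak`, `T_end`.
#' @export
place_keypoints <- function(rng, timing, params = list()) {
  stopifnot(inherits(timing, "cwm_cycle_timing"))
  p <- .merge_ranges(.timing_defaults(), params)
  tm <- timing
  for (i in seq_len(.MAX_REDRAW)) {
    b <- tm$L_pb
    R <- b + (tm$L_qrs - tm$L_ivc)  # IVC occupies exactly the R-S span
    S <- R + tm$L_ivc
    cpt <- rng_runif(rng, 1L, R, S)
    J <- S + tm$L_sj
    e <- J + tm$L_je
    f <- J + tm$L_st                # T-wave onset
    g <- f + rng_runif(rng, 1L, p$g_frac[1], p$g_frac[2]) * tm$L_twave
    t <- f + rng_runif(rng, 1L, p$t_frac[1], p$t_frac[2]) * tm$L_twave
    h <- f + rng_runif(rng, 1L, p$h_frac[1], p$h_frac[2]) * tm$L_twave
    T_end <- f + tm$L_twave
    # the relaxation trough k: from the second half of IVR to half of RPF
    k <- rng_runif(rng, 1L, T_end + tm$L_ivr / 2,
                   T_end + tm$L_ivr + tm$L_rpf / 2)
    pts <- c(0, b, cpt, S, J, e, f, g, t, h, k, tm$cycle_len)
    if (all(diff(pts) > 0))
      return(structure(list(
        P_peak = 0, b = b, c = cpt, S = S, J = J, e = e, f = f,
        g = g, t = t, h = h, k = k, cycle_end = tm$cycle_len,
        R = R, T_peak = f + 0.5 * tm$L_twave, T_end = T_end),
        class = "cwm_keypoints"))
  }
  stop("place_keypoints: could not satisfy monotonicity after ",
       .MAX_REDRAW, " redraws", call. = FALSE)
}

#' Sample the extremal velocities of one cycle
#'
#' Each landmark point of the piecewise model carries a sampled velocity;
#' segment shapes are rescaled onto these. Under the default
#' `inward_negative` sign convention the ejection extremes (`v_j`, `v_f`,
#' `v_t`) are negative (chest recedes during systole) while the filling
#' and atrial-systole peaks are positive. `v_rpe` and `v_rpfp` are
#' magnitudes. Units are normalized model velocity (m/s scale before
#' amplitude calibration).
#'
#' @inheritParams sample_cycle_length
#' @param params optional list of overrides for the velocity ranges.
#' @return a `cwm_velocity_keypoints` list with fields `v_b`, `v_afp`,
#'   `v_aop`, `v_j`, `v_e`, `v_f`, `v_g`, `v_t`, `v_h`, `v_ivrp`,
#'   `v_ivrv`, `v_rpf` and magnitudes `v_rpe`, `v_rpfp`.
#' @export
sample_velocity_keypoints <- function(rng, params = list()) {
  p <- .merge_ranges(.velocity_defaults(), params)
  v_rpfp <- rng_runif(rng, 1L, p$v_rpfp[1], p$v_rpfp[2])
  v_afp  <- rng_runif(rng, 1L, p$v_afp_frac[1], p$v_afp_frac[2]) * v_rpfp
  v_b    <- rng_runif(rng, 1L, p$v_b[1], p$v_b[2])
  v_aop  <- rng_runif(rng, 1L, p$v_aop[1], p$v_aop[2])
  v_rpe  <- rng_runif(rng, 1L, p$v_rpe[1], p$v_rpe[2])   # magnitude
  v_j    <- -rng_runif(rng, 1L, p$v_j_frac[1], p$v_j_frac[2]) * v_rpe
  v_e    <- rng_runif(rng, 1L, v_j, p$v_e_max)
  v_f    <- -rng_runif(rng, 1L, p$v_f_frac[1], p$v_f_frac[2]) * v_rpe
  v_g    <- rng_runif(rng, 1L, v_f, p$v_g_max)
  v_t    <- -rng_runif(rng, 1L, p$v_t_frac[1], p$v_t_frac[2]) * abs(v_f)
  v_h    <- rng_runif(rng, 1L, p$v_h[1], p$v_h[2])
  v_ivrp <- rng_runif(rng, 1L, p$v_ivrp[1], p$v_ivrp[2])
  v_ivrv <- rng_runif(rng, 1L, p$v_ivrv[1], p$v_ivrv[2])
  v_rpf  <- rng_runif(rng, 1L, p$v_rpf[1], p$v_rpf[2])
  structure(list(
    v_b = v_b, v_afp = v_afp, v_aop = v_aop, v_j = v_j, v_e = v_e,
    v_f = v_f, v_g = v_g, v_t = v_t, v_h = v_h, v_ivrp = v_ivrp,
    v_ivrv = v_ivrv, v_rpf = v_rpf, v_rpe = v_rpe, v_rpfp = v_rpfp),
    class = "cwm_velocity_keypoints")
}
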