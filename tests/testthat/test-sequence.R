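test_that("additive noise hits the requested SNR and 'none' is identity", {
  tr <- cwm_trace(sin(2 * pi * 1.2 * (0:19999) / 100), fs = 100)
  expect_identical(add_awgn(tr, "none", cwm_rng(1))$samples, tr$samples)
  noisy <- add_awgn(tr, 10, cwm_rng(1))
  resid <- noisy$samples - tr$samples
  snr_meas <- 10 * log10(mean(tr$samples^2) / mean(resid^2))
  expect_lt(abs(snr_meas - 10), 0.5)
  again <- add_awgn(tr, 10, cwm_rng(1))
  expect_identical(noisy$samples, again$samples)
  zero <- cwm_trace(rep(0, 10), fs = 100)
  expect_error(add_awgn(zero, 10, cwm_rng(1)), "zero-power")
})

test_that("HRV deviations are zero-mean and clipped to the normal range", {
  h <- sample_hrv_series(cwm_rng(8), 10000)
  expect_lte(max(abs(h$deviations)), 0.1)
  expect_lt(abs(mean(h$deviations)), 0.002)
  expect_true(h$sigma >= 0 && h$sigma <= 0.015)
  h0 <- sample_hrv_series(cwm_rng(8), 50, sigma_range = c(0, 0))
  expect_identical(h0$deviations, rep(0, 50))
})

test_that("retiming preserves endpoints, linearity and fiducial fractions", {
  ramp <- cwm_trace(seq(0, 1, length.out = 101), fs = 100,
                    fiducials = data.frame(cycle = 1L, marker = "x",
                                           time_s = 0.4))
  same <- retime_cycle(ramp, 101L)
  expect_equal(same$samples, ramp$samples)
  shrunk <- retime_cycle(ramp, 51L)
  expect_equal(shrunk$samples, seq(0, 1, length.out = 51), tolerance = 1e-12)
  expect_equal(shrunk$samples[c(1, 51)], c(0, 1))
  # fiducial at 40% of the cycle stays at 40%
  expect_equal(shrunk$fiducials$time_s / (51 / 100),
               ramp$fiducials$time_s / (101 / 100), tolerance = 1e-9)
  expect_error(retime_cycle(ramp, 1L), "target_samples")
  # the literal random-edit variant keeps length and endpoints
  re <- retime_cycle(ramp, 80L, method = "random_edit", rng = cwm_rng(2))
  expect_length(re$samples, 80L)
  expect_equal(re$samples[c(1, 80)], c(0, 1))
})

test_that("trapezoidal integration matches closed forms", {
  const <- cwm_trace(rep(0.01, 101), fs = 100, units = "velocity")
  d <- integrate_velocity(const)
  expect_equal(d$samples[1], 0)
  expect_equal(d$samples[101], 0.01, tolerance = 1e-9)
  expect_identical(d$units, "displacement")
  zero <- integrate_velocity(cwm_trace(rep(0, 50), fs = 100))
  expect_true(all(zero$samples == 0))
  fs <- 500
  sine <- cwm_trace(sin(2 * pi * (0:fs) / fs), fs = fs, units = "velocity")
  di <- integrate_velocity(sine)
  expect_lt(abs(di$samples[fs + 1]), 1 / fs)
  disp <- cwm_trace(1:10, fs = 10, units = "displacement")
  expect_error(integrate_velocity(disp), "velocity")
})

test_that("polynomial detrending removes a cubic exactly and is idempotent", {
  t <- seq(0, 10, by = 0.01)
  cubic <- 2 + 0.5 * t - 0.3 * t^2 + 0.04 * t^3
  tr <- cwm_trace(cubic, fs = 100, units = "displacement")
  expect_lt(max(abs(detrend_poly(tr, 3)$samples)), 1e-8)
  y <- sin(2 * pi * 1.2 * t) + cubic
  r1 <- detrend_poly(cwm_trace(y, fs = 100, units = "displacement"), 3)
  # independent regression oracle: lm residuals on the same basis
  oracle <- stats::residuals(stats::lm(y ~ poly(t, 3)))
  expect_lt(sqrt(mean((r1$samples - oracle)^2)), 1e-8)
  r2 <- detrend_poly(r1, 3)
  expect_lt(max(abs(r2$samples - r1$samples)), 1e-10)
  expect_error(detrend_poly(cwm_trace(1:3, fs = 1), 3), "length")
})

test_that("the long-sequence pipeline keeps its bookkeeping promises", {
  cfg <- cwm_config(seed = 31, n_cycles = 12, fs = 100)
  tr <- build_long_sequence(cfg)
  # duration equals the summed (sample-quantized) beat intervals
  expect_equal(length(tr$samples), sum(round(tr$meta$bbi * cfg$fs)))
  expect_lte(abs(length(tr$samples) / cfg$fs - sum(tr$meta$bbi)),
             12 * 0.5 / cfg$fs)
  # peak-to-peak amplitude lands in the resting-heartbeat window
  expect_gte(diff(range(tr$samples)), 0.5 - 1e-9)
  expect_lte(diff(range(tr$samples)), 1.1 + 1e-9)
  # beat intervals recovered from the cycle bounds equal the BBIs
  lens <- diff(c(tr$cycle_bounds, length(tr$samples) + 1L))
  expect_identical(as.integer(lens), as.integer(round(tr$meta$bbi * cfg$fs)))
  # fiducials: one P_peak per cycle, at the cycle start
  pp <- tr$fiducials[tr$fiducials$marker == "P_peak", ]
  expect_identical(nrow(pp), 12L)
  expect_equal(pp$time_s, (tr$cycle_bounds - 1) / cfg$fs, tolerance = 1e-9)
  # bit-for-bit determinism
  tr2 <- build_long_sequence(cfg)
  expect_identical(tr$samples, tr2$samples)
  expect_identical(tr$meta$bbi, tr2$meta$bbi)
  # residual drift after detrending is negligible
  t <- trace_time(tr)
  slope <- stats::coef(stats::lm(tr$samples ~ t))[2]
  expect_lt(abs(slope) / diff(range(tr$samples)), 1e-6)
})

test_that("duration-mode trims to the requested length", {
  cfg <- cwm_config(seed = 3, duration = 8, fs = 100)
  tr <- build_long_sequence(cfg)
  expect_length(tr$samples, 800L)
  expect_length(tr$meta$velocity, 800L)
  expect_true(all(tr$fiducials$time_s < 8))
})

test_that("the spectrum of a long run sits at the beat frequency", {
  # 20 s (~25 beats): long enough to resolve the fundamental, short enough
  # that the beat-length jitter (sd 0.08 s) stays within one FFT bin
  cfg <- cwm_config(seed = 21, duration = 20, fs = 50, snr_db = "none")
  tr <- build_long_sequence(cfg)
  sp <- amplitude_spectrum(tr)
  f0 <- 1 / mean(tr$meta$bbi)
  bin <- tr$fs / length(tr$samples)
  keep <- sp$freq_hz > 0.5 * f0          # skip residual baseline energy
  fpk <- sp$freq_hz[keep][which.max(sp$magnitude[keep])]
  expect_lte(abs(fpk - f0), bin + 1e-9)
  # harmonic magnitudes decrease with order
  mag_at <- function(f) {
    win <- abs(sp$freq_hz - f) <= 2 * bin
    max(sp$magnitude[win])
  }
  expect_gt(mag_at(fpk), mag_at(2 * fpk))
})
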