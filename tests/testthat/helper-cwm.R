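# Shared fixtures and independent oracles for the test suite.

# Brute-force DTW oracle: memoized recursion straight from the recurrence,
# independent of the package's dynamic-program implementation.
dtw_oracle <- function(A, B) {
  n <- length(A); m <- length(B)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    if (i == 0L || j == 0L) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- abs(A[i] - B[j]) + min(rec(i - 1L, j - 1L), rec(i - 1L, j),
                                rec(i, j - 1L))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# One fully sampled cycle (timing, keypoints, velocities, shape params).
make_cycle <- function(seed = 1, fs = 100, timing_over = list(),
                       vel_over = list()) {
  rng <- cwm_rng(seed)
  cl <- sample_cycle_length(rng, timing_over)
  tm <- sample_phase_durations(rng, cl, timing_over)
  sc <- place_keypoints(rng, tm, timing_over)
  vk <- sample_velocity_keypoints(rng, vel_over)
  sp <- sample_segment_params(rng, tm)
  list(rng = rng, timing = tm, schedule = sc, vk = vk, sp = sp, fs = fs)
}

# Synthesize one cycle, redrawing on sample-quantization failures the same
# way the pipeline does.
make_cycle_trace <- function(seed = 1, fs = 100) {
  for (s in seed + 0:50) {
    cyc <- make_cycle(s, fs)
    tr <- tryCatch(
      synthesize_cycle_velocity(cyc$timing, cyc$schedule, cyc$vk, cyc$sp, fs),
      error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  stop("make_cycle_trace: no synthesizable cycle found")
}
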