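test_that("rescale_to_interval is the stated affine map", {
  expect_equal(rescale_to_interval(c(0, 0.5, 1), -0.05, 0.02),
               c(-0.05, -0.015, 0.02))
  x <- rnorm(50)
  expect_equal(rescale_to_interval(x, min(x), max(x)), x)
  expect_equal(rescale_to_interval(c(3, 3, 3), 0, 2), c(1, 1, 1))
  expect_error(rescale_to_interval(numeric(0), 0, 1), "empty")
  expect_error(rescale_to_interval(1:3, 1, 0), "v_max")
})

test_that("segment shapes match direct formula evaluation pointwise", {
  fs <- 1000
  set.seed(101)
  for (i in 1:20) {
    L <- runif(1, 0.05, 0.3)
    t <- (seq_len(round(L * fs)) - 1) / fs
    th <- runif(1, pi / 12, pi / 4); al <- runif(1, 4 / 3, 2)
    expect_equal(seg_sinusoid_pb(L, fs, th, al),
                 sin(2 * pi * t / (al * L) + th), tolerance = 1e-12)
    ag <- runif(1, 1 / 6, 3 / 5)
    expect_equal(seg_cosine_gt(L, fs, ag),
                 cos(2 * pi * (ag / L) * t), tolerance = 1e-12)
    rt <- runif(1, 1.5, 2)
    expect_equal(seg_sine_th(L, fs, rt),
                 sin(2 * pi * t / (rt * L) + 3 * pi / 2), tolerance = 1e-12)
    tg <- runif(1, 0.001, 0.1)
    expect_equal(seg_exp_decay(L, fs, tg),
                 exp(-(-log(tg) / L) * t), tolerance = 1e-12)
    sg <- runif(1, 0.01, 0.2)
    expect_equal(seg_rayleigh(L, fs, sg),
                 (t / sg^2) * exp(-t^2 / (2 * sg^2)), tolerance = 1e-12)
    mu <- runif(1, 0.02, L); gm <- runif(1, -0.5, 0.2)
    z <- (t - mu) / sg
    expect_equal(seg_skew_gauss_hk(L, fs, mu, sg, gm),
                 (1 / sqrt(2 * pi * sg^2)) * exp(-z^2 / 2) * (1 - gm * z^3),
                 tolerance = 1e-12)
    sat <- runif(1, 0.85, 0.99)
    k <- 2 * log(sat / (1 - sat)) / L
    expect_equal(seg_logistic(L, fs, sat),
                 1 / (1 + exp(-k * (t - L / 2))), tolerance = 1e-12)
  }
})

test_that("logistic saturation solves the endpoint condition", {
  y <- seg_logistic(0.1, 1000, 0.9)
  # k = 2 ln(9) / L for 0.9 saturation
  expect_equal(2 * log(0.9 / 0.1) / 0.1, 43.944, tolerance = 1e-3)
  expect_equal(y[1], 0.1, tolerance = 1e-12)       # value at t = 0
  expect_equal(y[51], 0.5, tolerance = 1e-12)      # midpoint t = L/2
  expect_true(all(diff(y) > 0))
  y99 <- seg_logistic(0.2, 1000, 0.99)
  expect_equal(y99[1], 0.01, tolerance = 1e-12)
  expect_error(seg_logistic(0.1, 1000, 0.4), "saturation")
})

test_that("exponential decay hits its target at the segment end", {
  expect_equal(-log(0.01) / 0.05, 92.103, tolerance = 1e-3)
  y <- seg_exp_decay(0.05, 1000, 0.01)
  expect_equal(y[1], 1)
  expect_true(all(diff(y) < 0))
  # extrapolating one step past the grid end lands exactly on target
  expect_equal(y[length(y)] * exp(log(0.01) / 0.05 / 1000), 0.01,
               tolerance = 1e-12)
  expect_error(seg_exp_decay(0.05, 1000, 1.5), "target")
})

test_that("Rayleigh shape peaks at t = sigma with the closed-form value", {
  sg <- 0.07
  y <- seg_rayleigh(0.3, 2000, sg)
  t <- (seq_along(y) - 1) / 2000
  expect_equal(y[1], 0)
  expect_equal(t[which.max(y)], sg, tolerance = 1e-3)
  expect_equal(max(y), exp(-0.5) / sg, tolerance = 1e-4)
})

test_that("cosine and shifted-sine segments start at their extremes", {
  y <- seg_cosine_gt(0.1, 1000, 0.5)
  expect_equal(y[1], 1)
  expect_true(all(diff(y) < 0))            # monotone for alpha_gt <= 1/2
  # at t = L the phase is pi: cos(pi) = -1
  expect_equal(cos(2 * pi * 0.5), -1)
  s <- seg_sine_th(0.1, 1000, 2)
  expect_equal(s[1], -1)
  q <- floor(length(s) * 2 / 4)            # first quarter of period r_th*L
  expect_true(all(diff(s[seq_len(min(q, length(s)))]) > 0))
})

test_that("skewed Gaussian symmetry and skew ratio follow the cubic factor", {
  y <- seg_skew_gauss_hk(0.2, 1000, mu = 0.1, sigma = 0.03, gamma = 0)
  t <- (seq_along(y) - 1) / 1000
  i_mu <- which.min(abs(t - 0.1))
  d <- 20
  expect_equal(y[i_mu + d], y[i_mu - d], tolerance = 1e-9)
  expect_equal(y[i_mu], 1 / sqrt(2 * pi * 0.03^2), tolerance = 1e-6)
  ys <- seg_skew_gauss_hk(0.2, 1000, mu = 0.1, sigma = 0.03, gamma = -0.5)
  i_p <- which.min(abs(t - 0.13)); i_m <- which.min(abs(t - 0.07))
  expect_equal(ys[i_p] / ys[i_m], 3, tolerance = 1e-6)
})

test_that("segments reject degenerate inputs", {
  expect_error(seg_rayleigh(-1, 100, 0.1))
  expect_error(seg_rayleigh(0.1, 100, -1), "sigma")
  expect_error(seg_sinusoid_pb(0.001, 100, pi / 6, 1.5), "2 samples")
})

test_that("an assembled cycle honors the rescale contract segment by segment", {
  fs <- 200
  tr <- make_cycle_trace(seed = 2, fs = fs)
  tm <- tr$meta$timing; vk <- tr$meta$velocities
  expect_equal(length(tr$samples), round(tm$cycle_len * fs))
  idx <- tr$meta$segment_start_index
  ends <- stats::setNames(c(idx[-1] - 1L, length(tr$samples)), names(idx))
  seg <- function(nm) tr$samples[idx[[nm]]:ends[[nm]]]
  tol <- 1e-12
  expect_equal(range(seg("pb")), c(vk$v_b, vk$v_afp), tolerance = tol)
  expect_equal(range(seg("bc")), c(vk$v_b, vk$v_aop), tolerance = tol)
  expect_equal(range(seg("cj")), c(vk$v_j, vk$v_aop), tolerance = tol)
  expect_equal(range(seg("je")), c(vk$v_j, vk$v_e), tolerance = tol)
  expect_equal(range(seg("ef")), c(vk$v_f, vk$v_e), tolerance = tol)
  expect_equal(range(seg("fg")), c(vk$v_f, vk$v_g), tolerance = tol)
  fg <- seg("fg")
  expect_equal(range(seg("gt")), c(vk$v_t, fg[length(fg)]), tolerance = tol)
  expect_equal(range(seg("th")), c(vk$v_t, vk$v_h), tolerance = tol)
  expect_equal(range(seg("hk")), c(vk$v_ivrv, vk$v_ivrp), tolerance = tol)
  expect_equal(range(seg("fill")), c(0, vk$v_rpf), tolerance = tol)
  # ten contiguous segments, no gaps or overlaps
  expect_identical(unname(idx[1]), 1L)
  expect_identical(unname(ends[-10] + 1L), unname(idx[-1]))
  # deepest ejection keypoint is the cycle minimum
  expect_equal(min(tr$samples), -max(abs(vk$v_j), abs(vk$v_f), abs(vk$v_t)),
               tolerance = tol)
  # velocity starts and ends small relative to the ejection extreme
  expect_lt(abs(tr$samples[1]), 0.1)
  expect_lt(abs(tr$samples[length(tr$samples)]), 0.1)
})
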