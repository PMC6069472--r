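test_that("smoothing has unit DC gain and the analytic band behaviour", {
  expect_equal(smooth_signal(rep(3.7, 50), fs = 30), rep(3.7, 50))
  expect_error(smooth_signal(rnorm(50), fs = 2), "Nyquist")
  expect_error(smooth_signal(rnorm(3), fs = 30), "4 samples")
  # squared closed-form magnitude of the first-order digital Butterworth
  # (bilinear design, cutoff 1 Hz): applied forward and backward the filter
  # attenuates by |H(f)|^2 = 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^2)
  fs <- 30
  gain2 <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * 1 / fs))^2)
  tt <- (0:599) / fs
  # 0.1 Hz sine: amplitude preserved within 2%
  x <- sin(2 * pi * 0.1 * tt)
  s <- smooth_signal(x, fs)
  mid <- 150:450
  expect_equal(max(abs(s[mid])), gain2(0.1), tolerance = 0.02)
  expect_gt(max(abs(s[mid])), 0.97)
  # fast sine (7.3 Hz, incommensurate with fs so samples sweep the phase):
  # attenuated to the squared closed-form response within 10%
  x10 <- sin(2 * pi * 7.3 * tt)
  s10 <- smooth_signal(x10, fs)
  expect_equal(max(abs(s10[mid])), gain2(7.3), tolerance = 0.1 * gain2(7.3))
  # zero phase: the smoothed peak of a symmetric bump does not move
  bump <- exp(-(tt - 10)^2 / 2)
  expect_equal(which.max(smooth_signal(bump, fs)), which.max(bump), tolerance = 1)
})

test_that("differentiation is exact on linear signals and accurate on sines", {
  expect_equal(differentiate(rep(2, 10), 30), rep(0, 10))
  fs <- 20
  ramp <- 3 * (0:49) / fs
  v <- differentiate(ramp, fs)
  expect_equal(v, rep(3, 50))  # one-sided ends are also exact for a line
  tt <- (0:399) / 100
  s <- sin(2 * pi * tt)
  v <- differentiate(s, 100)
  expect_equal(v[10:390], 2 * pi * cos(2 * pi * tt[10:390]),
               tolerance = 1e-2)
  expect_error(differentiate(1, 30), "2 samples")
})

test_that("the 16 descriptors of a constant signal are degenerate as specified", {
  d <- describe(rep(4.2, 20), fs = 10)
  expect_length(d, 16)
  expect_equal(unname(d[c("max", "min", "mean", "median")]), rep(4.2, 4))
  expect_equal(unname(d[c("range", "sd", "iqr", "idr", "mad")]), rep(0, 5))
  expect_equal(unname(d[c("dur_mean", "dur_mid", "seg_mean", "seg_mid")]),
               rep(0, 4))
  expect_equal(unname(d[c("area", "area_quot", "t_peak")]), rep(0, 3))
  expect_error(describe(numeric(0), 10), "empty")
})

test_that("descriptors match the brute-force oracle on a triangular pulse", {
  x <- c(0, 1, 2, 3, 4, 3, 2, 1, 0, 0)
  expect_equal(describe(x, fs = 5), naive_describe(x, fs = 5))
  # spot-check a few against hand arithmetic
  d <- describe(x, fs = 5)
  expect_equal(unname(d["max"]), 4)
  expect_equal(unname(d["t_peak"]), 4 / 5)
  expect_equal(unname(d["area"]), sum(x) / 5)
  expect_equal(unname(d["seg_mean"]), 1)
  expect_equal(unname(d["dur_mid"]), sum(x > 0.8) / 5)
})

test_that("descriptors match the oracle on 100 seeded random signals", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                cumsum(rnorm(n)),
                round(rnorm(n), 1))  # ties exercise quantiles and runs
    fs <- sample(c(10, 25, 30), 1)
    got <- describe(x, fs)
    want <- naive_describe(x, fs)
    expect_equal(got[c("max", "min", "range", "t_peak", "dur_mean", "dur_mid",
                       "seg_mean", "seg_mid")],
                 want[c("max", "min", "range", "t_peak", "dur_mean", "dur_mid",
                        "seg_mean", "seg_mid")])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("descriptor invariances: level shift and time scaling", {
  set.seed(5)
  x <- cumsum(rnorm(40))
  d0 <- describe(x, 20)
  d1 <- describe(x + 11.5, 20)
  loc <- c("max", "min", "mean", "median")
  expect_equal(d1[loc], d0[loc] + 11.5)
  rest <- setdiff(descriptor_names(), loc)
  expect_equal(d1[rest], d0[rest], tolerance = 1e-9)
  # halving fs doubles durations, peak times and areas; counts unchanged
  d2 <- describe(x, 10)
  expect_equal(unname(d2[c("dur_mean", "dur_mid", "t_peak", "area")]),
               unname(2 * d0[c("dur_mean", "dur_mid", "t_peak", "area")]))
  expect_equal(d2[c("seg_mean", "seg_mid")], d0[c("seg_mean", "seg_mid")])
})

test_that("build_stream assembles 48 values per signal in fixed block order", {
  set.seed(8)
  sigs <- list(alpha = rnorm(30), beta = cumsum(rnorm(30)))
  v <- build_stream(sigs, fs = 30)
  expect_length(v, 96)
  expect_equal(names(v)[1:3], c("alpha.s.max", "alpha.s.min", "alpha.s.mean"))
  expect_equal(names(v)[49], "beta.s.max")
  one <- build_stream(sigs["alpha"], fs = 30)
  expect_length(one, 48)
  # permuting input signal order permutes the 48-blocks
  v2 <- build_stream(sigs[c("beta", "alpha")], fs = 30)
  expect_equal(unname(v2[1:48]), unname(v[49:96]))
  expect_equal(unname(v2[49:96]), unname(v[1:48]))
  # inconsistent lengths are rejected
  expect_error(build_stream(list(a = rnorm(10), b = rnorm(12)), fs = 30),
               "length")
  # geometry streams have the printed dimensions
  sig <- geometry_signals(toy_sequence(8))
  expect_length(build_stream(sig[deformation_names()], fs = 30), 528)
  expect_length(build_stream(sig[pose_names()], fs = 30), 384)
})
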