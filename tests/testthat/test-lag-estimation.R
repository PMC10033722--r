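test_that("direct cross-correlation matches hand-computed values", {
  c0 <- cross_correlate_direct(1, 1)
  expect_equal(c0$lags, 0L)
  expect_equal(c0$values, 1)
  c1 <- cross_correlate_direct(c(1, 2), c(1, 2))
  expect_equal(c1$lags, -1L:1L)
  expect_equal(c1$values, c(2, 5, 2))
  # frozen oracle (independent enumeration of all shifts)
  c2 <- cross_correlate_direct(c(1, 2, 3, 0, 1), c(0, 1, 2, 3, 0))
  expect_equal(c2$lags, -4L:4L)
  expect_equal(c2$values, c(0, 1, 2, 6, 8, 14, 8, 3, 0))
  expect_error(cross_correlate_direct(numeric(0), 1), "empty")
})

test_that("reversing argument order negates the lag axis", {
  set.seed(5)
  a <- rnorm(17); b <- rnorm(23)
  ab <- cross_correlate_direct(a, b)
  ba <- cross_correlate_direct(b, a)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-12)
  expect_equal(ab$lags, -rev(ba$lags))
})

test_that("FFT cross-correlation equals the direct oracle", {
  # the frozen 5-sample case, plus the delayed-impulse sign convention
  cf <- cross_correlate_fft(c(1, 2, 3, 0, 1), c(0, 1, 2, 3, 0))
  expect_equal(cf$values, c(0, 1, 2, 6, 8, 14, 8, 3, 0), tolerance = 1e-12)
  imp <- cross_correlate_fft(c(0, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(imp$lags[which.max(imp$values)], 1L)
  # randomized equivalence, mixed lengths up to 256
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(1:256, 1))
    b <- rnorm(sample(1:256, 1))
    f <- cross_correlate_fft(a, b)
    d <- cross_correlate_direct(a, b)
    expect_equal(f$lags, d$lags)
    scale <- max(abs(d$values))
    expect_lt(max(abs(f$values - d$values)) / scale, 1e-9)
  }
  # autocorrelation peaks at zero lag
  x <- smooth_noise(512, 2)
  ac <- cross_correlate_fft(x, x)
  expect_equal(ac$lags[which.max(ac$values)], 0L)
  expect_equal(max(ac$values) / ac$norm, 1, tolerance = 1e-12)
})

test_that("lag windowing keeps only the requested range", {
  corr <- correlation_function(-5L:5L, c(1:5, 10, 5:1))
  expect_equal(restrict_lags(corr, -5, 5)$values, corr$values)
  # a window that excludes the global maximum finds the windowed max
  w <- restrict_lags(corr, 2, 5)
  expect_equal(peak_lag(w)$lag_samples, 2)
  # single-lag boundary window
  s <- restrict_lags(corr, 3, 4)
  expect_equal(s$lags, 3L:4L)
  expect_error(restrict_lags(corr, 4, 4), "min_lag")
  expect_error(restrict_lags(corr, 20, 30), "empty")
})

test_that("peak location breaks ties toward small positive lags", {
  tie <- correlation_function(-4L:4L, c(0, 3, 0, 0, 1, 0, 0, 3, 0))
  expect_equal(peak_lag(tie)$lag_samples, 3) # equal maxima at -3 and +3
  expect_error(peak_lag(correlation_function(0L:3L, rep(1, 4))), "unique")
  # exact integer recovery with peak_corr = 1 for a pure shifted copy
  x <- smooth_noise(4096, 9)
  y <- shift_int(x, 37)
  pk <- peak_lag(cross_correlate_fft(x[1:3500], y[1:3500]), fs = 1000)
  expect_equal(pk$lag_samples, 37)
  expect_equal(pk$delay_s, 0.037)
})

test_that("integer shifts are recovered exactly across four decades", {
  n <- 32768
  x <- smooth_noise(n, 13)
  for (k in c(1L, 3L, 17L, 123L, 999L, 4096L, 10000L)) {
    pk <- peak_lag(cross_correlate_fft(x, shift_int(x, k)))
    expect_identical(as.integer(pk$lag_samples), k)
  }
})

test_that("sub-sample refinement resolves fractional delays below 0.1 sample", {
  fs <- 1000
  x <- smooth_noise(8192, 4)
  y <- propagate_constant(x, fs, 10.5 / fs)
  corr <- cross_correlate_fft(x, y)
  coarse <- peak_lag(corr, fs = fs, subsample = FALSE)
  fine <- peak_lag(corr, fs = fs, subsample = TRUE)
  expect_true(coarse$lag_samples %in% c(10, 11))
  expect_lt(abs(fine$lag_samples - 10.5), 0.1)
})

test_that("velocity conversion follows v = d / T with the display-rounding path", {
  # the oscilloscope worked example: 65006 samples at 0.5 GHz over 0.55 m
  lag <- lag_estimate(65006, fs = 0.5e9)
  expect_identical(lag$sampling_time_s, 2e-9)
  expect_equal(round(lag$delay_s * 1000, 2), 0.13) # T in ms
  vm <- lag_to_velocity(lag, 0.55, delay_rounding = 1e-5)
  expect_equal(round(vm$velocity), 4231)
  # full precision differs: 0.55 / 0.130012 ms
  expect_equal(lag_to_velocity(lag, 0.55)$velocity, 0.55 / 1.30012e-4,
               tolerance = 1e-12)
  # exact division example: 2000 samples at 5 MHz over 0.6 m
  expect_equal(lag_to_velocity(lag_estimate(2000, 5e6), 0.6)$velocity, 1500)
  expect_error(lag_to_velocity(lag_estimate(0, 5e6), 0.6), "non-physical")
  expect_error(lag_to_velocity(lag_estimate(-10, 5e6), 0.6), "non-physical")
  expect_error(lag_to_velocity(lag_estimate(10, NA), 0.6), "sampling rate")
})

test_that("end-to-end measurement recovers implanted velocities", {
  tpl <- beat_template()
  # integer-sample delay: exact recovery
  sim <- simulate_recording(tpl, fs = 5e4, n_beats = 3, distance = 0.6,
                            velocity = 1500, snr_db = Inf, seed = 1)
  m <- run_measurement(sim$recording)
  expect_identical(as.integer(m$lag$lag_samples), 20L)
  expect_equal(m$velocity, 1500)
  expect_true(m$quality$accepted)
  # fractional-delay truth: recovery within the one-sample quantization bound
  v_true <- 1600 # 18.75-sample delay at 50 kHz
  sim2 <- simulate_recording(tpl, 5e4, 3, 0.6, v_true, snr_db = Inf, seed = 1)
  m2 <- run_measurement(sim2$recording)
  expect_lt(abs(m2$velocity - v_true), v_true^2 / (0.6 * 5e4))
  # distal channel leading: flagged as non-physical, not silently accepted
  swapped <- two_channel_recording(sim$recording$ch2, sim$recording$ch1,
                                   fs = 5e4, distance = 0.6)
  m3 <- run_measurement(swapped)
  expect_false(m3$quality$accepted)
  expect_match(m3$quality$reject_reason, "non-physical")
  expect_true(is.na(m3$velocity))
})

test_that("median recovery stays within 5% under measurement noise", {
  # reduced-scale noisy recovery: 100 kHz at 25 dB has a comparable
  # in-band noise floor to the full-scale 1 MHz / 12.45 dB condition
  fs <- 1e5
  tpl <- beat_template()
  clean <- render_ecg(tpl, fs, 3)
  delayed <- propagate_constant(clean, fs, 0.6 / 1500)
  v <- vapply(1:7, function(seed) {
    ch1 <- add_white_noise(clean, 25, seed = seed * 2L)
    ch2 <- add_white_noise(delayed, 25, seed = seed * 2L + 1L)
    rec <- two_channel_recording(ch1, ch2, fs, 0.6)
    run_measurement(rec)$velocity
  }, numeric(1))
  expect_lt(abs(stats::median(v) - 1500) / 1500, 0.05)
})
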