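test_that("beat template validates morphology invariants", {
  expect_s3_class(beat_template(), "beat_template")
  # R must carry the largest positive amplitude
  expect_error(beat_template(amplitude_mv = c(P = 2, Q = -0.1, R = 1,
                                              S = -0.1, T = 0.3)), "R wave")
  expect_error(beat_template(width_s = c(P = 0.025, Q = 0, R = 0.012,
                                         S = 0.008, T = 0.04)), "width")
  expect_error(beat_template(rr_interval_s = 0.1), "span")
})

test_that("rendered ECG has the constructed geometry", {
  # null template renders all zeros
  tpl0 <- beat_template(amplitude_mv = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_true(all(render_ecg(tpl0, 1000, 2) == 0))
  # single R-only beat: global maximum at the R centre sample, value 1 mV
  tpl <- beat_template(amplitude_mv = c(P = 0, Q = 0, R = 1, S = 0, T = 0),
                       width_s = c(P = 0.025, Q = 0.01, R = 0.01,
                                   S = 0.01, T = 0.04))
  x <- render_ecg(tpl, 2000, 1)
  expect_equal(which.max(x), round(0.5 * 2000) + 1)
  expect_equal(max(x), 1)
  # three beats at rr = 1 s: exactly 3 local maxima above half the max
  y <- render_ecg(beat_template(), 5000, 3)
  pk <- which(diff(sign(diff(y))) < 0) + 1L
  expect_equal(sum(y[pk] > 0.5 * max(y)), 3)
  # undersampling error names the narrowest wave
  expect_error(render_ecg(beat_template(), 1000, 1), "Q wave")
  # deterministic
  expect_identical(render_ecg(beat_template(), 5000, 2),
                   render_ecg(beat_template(), 5000, 2))
})

test_that("constant-delay propagation is exact for integer and fractional delays", {
  fs <- 1000
  n <- 512
  imp <- numeric(n); imp[100] <- 1
  # integer shift of an impulse
  out <- propagate_constant(imp, fs, 7 / fs)
  expect_equal(which.max(out), 107)
  expect_equal(max(out), 1, tolerance = 1e-9)
  # zero delay is the identity
  expect_identical(propagate_constant(imp, fs, 0), imp)
  # tone acquires phase -2*pi*f0*tau: compare against the analytic delay of a
  # Gaussian-windowed sinusoid (smooth at the record edges, so the only
  # discrepancy left is the fractional-delay operator itself)
  f0 <- 40; tau <- 0.0037
  t <- (seq_len(n) - 1) / fs
  burst <- function(tt) exp(-((tt - 0.25) / 0.05)^2) * sin(2 * pi * f0 * tt)
  x <- burst(t)
  y <- propagate_constant(x, fs, tau)
  ref <- burst(t - tau)
  expect_lt(max(abs(y - ref)), 1e-6)
  # energy preserved
  expect_equal(mean(y^2), mean(ref^2), tolerance = 1e-6)
  expect_error(propagate_constant(imp, fs, 1), "longer than the record")
  expect_error(propagate_constant(imp, fs, -1e-3), "non-negative")
})

test_that("dispersive propagation reduces to a constant delay for flat spectra", {
  fs <- 2000
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2^10:2^14, 1)
    x <- smooth_noise(n, seed)
    set.seed(seed + 100)
    eps <- 10^stats::runif(1, 1, 8)
    sp <- permittivity_spectrum(10, eps)
    d <- stats::runif(1, 1, 100) # exaggerated distance: fractional-delay regime
    delay <- d * sqrt(eps) / speed_of_light
    a <- propagate_dispersive(x, fs, d, sp)
    b <- propagate_constant(x, fs, delay)
    expect_lt(sqrt(mean((a - b)^2)), 1e-8)
  }
})

test_that("dispersive propagation delays a narrowband tone by d / v(f0)", {
  fs <- 4000; n <- 8192
  t <- (seq_len(n) - 1) / fs
  f0 <- 50 # 80 samples per cycle
  x <- sin(2 * pi * f0 * t)
  sp <- two_point_spectrum()
  d <- 20 # long path so the delay is well above the phase-noise floor
  tau <- as.numeric(theoretical_delay(d, f0, sp))
  y <- propagate_dispersive(x, fs, d, sp)
  # lock-in phase over an integer number of cycles away from the edges
  interior <- 401:(400 + 90 * 80)
  lockin <- exp(-2i * pi * f0 * t[interior])
  dphi <- Arg(sum(y[interior] * lockin) * Conj(sum(x[interior] * lockin)))
  expect_equal(-dphi / (2 * pi * f0), tau, tolerance = 0.02)
})

test_that("near-zero delay leaves the signal essentially unchanged", {
  x <- smooth_noise(2048, 3)
  y <- propagate_dispersive(x, 1000, 1e-3, permittivity_spectrum(10, 1))
  expect_lt(max(abs(y - x)), 1e-6)
})

test_that("white noise hits the requested SNR and is seed-reproducible", {
  x <- render_ecg(beat_template(), 5000, 2)
  for (snr in c(5, 12.45, 30)) {
    y <- add_white_noise(x, snr, seed = 42)
    noise <- y - x
    achieved <- 10 * log10(mean(x^2) / mean(noise^2))
    expect_equal(achieved, snr, tolerance = 0.01)
  }
  # 12.45 dB corresponds to a signal/noise power ratio of 17.58
  y <- add_white_noise(x, 12.45, seed = 7)
  expect_equal(mean(x^2) / mean((y - x)^2), 10^1.245, tolerance = 0.03 * 17.58)
  expect_identical(add_white_noise(x, 10, seed = 9),
                   add_white_noise(x, 10, seed = 9))
  expect_false(identical(add_white_noise(x, 10, seed = 9),
                         add_white_noise(x, 10, seed = 10)))
  expect_identical(add_white_noise(x, Inf, seed = 1), x)
  expect_error(add_white_noise(numeric(100), 10, seed = 1), "all-zero")
})

test_that("power-line interference is gated and has the stated period", {
  fs <- 10000
  x <- numeric(fs) # 1 s of silence
  expect_identical(add_powerline(x, fs, 54, amplitude = 0), x)
  expect_identical(add_powerline(x, fs, 54, 0.05, gate = logical(fs)), x)
  expect_error(add_powerline(x, fs, 6000, 0.05), "Nyquist")
  # ungated 54 Hz tone: successive positive peaks spaced ~18.5 ms
  y <- add_powerline(x, fs, 54, 0.05)
  pk <- which(diff(sign(diff(y))) < 0) + 1L
  pk <- pk[y[pk] > 0.04]
  expect_equal(mean(diff(pk)) / fs, 1 / 54, tolerance = 0.01)
  # gating confines the tone to the mask support
  gate <- qrs_mask(length(x), fs, qrs_times = 0.5, half_width_s = 0.05)
  z <- add_powerline(x, fs, 54, 0.05, gate = gate)
  expect_true(all(z[!gate] == 0))
  expect_gt(max(abs(z[gate])), 0.04)
})

test_that("simulated recordings carry exact, reproducible ground truth", {
  tpl <- beat_template()
  sim <- simulate_recording(tpl, fs = 5e4, n_beats = 3, distance = 0.6,
                            velocity = 1500, snr_db = Inf, seed = 1)
  # 0.6 m at 1500 m/s is 0.4 ms: an exact 20-sample delay at 50 kHz
  expect_identical(sim$truth$true_delay_s * 5e4, 20)
  expect_identical(sim$truth$true_velocity * sim$truth$true_delay_s, 0.6)
  expect_equal(sim$truth$qrs_times, c(0.5, 1.5, 2.5))
  # bit-reproducible under the same seed, different under another
  again <- simulate_recording(tpl, fs = 5e4, n_beats = 3, distance = 0.6,
                              velocity = 1500, snr_db = Inf, seed = 1)
  expect_identical(sim$recording$ch1, again$recording$ch1)
  expect_identical(sim$recording$ch2, again$recording$ch2)
  noisy1 <- simulate_recording(tpl, 5e4, 3, 0.6, 1500, snr_db = 12.45, seed = 5)
  noisy2 <- simulate_recording(tpl, 5e4, 3, 0.6, 1500, snr_db = 12.45, seed = 5)
  noisy3 <- simulate_recording(tpl, 5e4, 3, 0.6, 1500, snr_db = 12.45, seed = 6)
  expect_identical(noisy1$recording$ch2, noisy2$recording$ch2)
  expect_false(identical(noisy1$recording$ch2, noisy3$recording$ch2))
  # the two channels receive independent noise streams
  n1 <- noisy1$recording$ch1 - sim$recording$ch1
  n2 <- noisy1$recording$ch2 - sim$recording$ch2
  expect_lt(abs(stats::cor(n1, n2)), 0.05)
  # degenerate template: SNR undefined
  tpl0 <- beat_template(amplitude_mv = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_error(simulate_recording(tpl0, 5e4, 1, 0.6, 1500,
                                  snr_db = 12.45, seed = 1), "all-zero")
})
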