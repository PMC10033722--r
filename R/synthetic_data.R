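#' Parametric single-beat ECG template
#'
#' A sum-of-Gaussians beat: one bump per wave (P, Q, R, S, T), each with an
#' amplitude in mV, a centre offset from the R peak in seconds and a Gaussian
#' width (sigma) in seconds. Defaults resemble a lead-II morphology; they are
#' conveniences, not physiological claims.
#'
#' @param amplitude_mv Named numeric vector of wave amplitudes (mV) in order
#'   P, Q, R, S, T.
#' @param center_s Wave centres relative to the R peak, seconds.
#' @param width_s Gaussian sigma of each wave, seconds, all > 0.
#' @param rr_interval_s Beat-to-beat interval in seconds; must exceed the
#'   total span of the beat.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(
    amplitude_mv = c(P = 0.15, Q = -0.15, R = 1.0, S = -0.2, T = 0.3),
    center_s     = c(P = -0.22, Q = -0.035, R = 0, S = 0.035, T = 0.30),
    width_s      = c(P = 0.025, Q = 0.008, R = 0.012, S = 0.008, T = 0.04),
    rr_interval_s = 1.0) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitude_mv, center_s, width_s))
    if (length(v) != 5L || !is.numeric(v)) stop("each wave field needs 5 numeric values")
  names(amplitude_mv) <- names(center_s) <- names(width_s) <- waves
  if (any(width_s <= 0)) stop("wave widths must be positive")
  if (!is.numeric(rr_interval_s) || rr_interval_s <= 0)
    stop("rr_interval_s must be positive")
  span <- diff(range(center_s - 4 * width_s, center_s + 4 * width_s))
  if (rr_interval_s <= span)
    stop("rr_interval_s must exceed the beat span (", signif(span, 3), " s)")
  pos <- amplitude_mv[amplitude_mv > 0]
  if (length(pos) && (!"R" %in% names(pos) || max(pos) > amplitude_mv[["R"]]))
    stop("the R wave must carry the largest positive amplitude")
  structure(list(amplitude_mv = amplitude_mv, center_s = center_s,
                 width_s = width_s, rr_interval_s = rr_interval_s),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat("<beat_template> rr =", x$rr_interval_s, "s\n")
  print(data.frame(amplitude_mV = x$amplitude_mv, center_s = x$center_s,
                   width_s = x$width_s))
  invisible(x)
}

#' Render a noiseless multi-beat ECG trace
#'
#' Sums the template's Gaussian bumps for `n_beats` beats spaced
#' `rr_interval_s` apart. The record spans `n_beats * rr` seconds with the
#' k-th R peak at `(k - 1/2) * rr`. Deterministic given its inputs.
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency in Hz. Must be high enough that the narrowest
#'   wave's sigma covers at least 20 samples.
#' @param n_beats Number of beats, >= 1.
#' @return Numeric vector of samples in mV.
#' @export
render_ecg <- function(template, fs, n_beats = 3L) {
  stopifnot(inherits(template, "beat_template"), fs > 0, n_beats >= 1)
  wmin <- which.min(template$width_s)
  if (template$width_s[wmin] * fs < 20 && any(template$amplitude_mv != 0))
    stop(sprintf(
      "undersampled: %s wave sigma (%g s) spans fewer than 20 samples at fs = %g Hz",
      names(template$width_s)[wmin], template$width_s[wmin], fs))
  rr <- template$rr_interval_s
  n <- round(n_beats * rr * fs)
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (k in seq_len(n_beats)) {
    r_time <- (k - 0.5) * rr
    for (w in seq_along(template$amplitude_mv)) {
      a <- template$amplitude_mv[[w]]
      if (a == 0) next
      mu <- r_time + template$center_s[[w]]
      sig <- template$width_s[[w]]
      # restrict to +/- 6 sigma: exp() on the full grid is the cost driver
      i0 <- max(1L, floor((mu - 6 * sig) * fs) + 1L)
      i1 <- min(n, ceiling((mu + 6 * sig) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      out[idx] <- out[idx] + a * exp(-0.5 * ((t[idx] - mu) / sig)^2)
    }
  }
  out
}

r_peak_times <- function(template, n_beats) {
  (seq_len(n_beats) - 0.5) * template$rr_interval_s
}

# Fractional-delay phase ramp over padded length m; returns the complex
# transfer function with a real Nyquist bin so the inverse transform is real.
delay_transfer <- function(m, fs, delay_per_bin) {
  H <- exp(-2i * pi * freq_bins(m, fs) * delay_per_bin)
  if (m %% 2L == 0L)
    H[m / 2L + 1L] <- cos(2 * pi * (fs / 2) * delay_per_bin[[m / 2L + 1L]])
  H
}

freq_bins <- function(m, fs) {
  k <- 0:(m - 1L)
  ifelse(k <= m / 2, k, k - m) * fs / m
}

#' Delay a signal by a constant (possibly fractional) time
#'
#' Applies the exact all-pass delay `exp(-i 2 pi f tau)` in the frequency
#' domain, so non-integer sample delays are rendered without interpolation
#' error. The record is zero-padded past the delay before the transform to
#' avoid circular wrap-around, then trimmed back to its original length.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency, Hz.
#' @param delay Delay in seconds, >= 0 and shorter than the record.
#' @return Delayed signal, same length as `x`.
#' @export
propagate_constant <- function(x, fs, delay) {
  if (!is.numeric(delay) || length(delay) != 1L || delay < 0)
    stop("delay must be a single non-negative number")
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (delay >= n / fs) stop("delay longer than the record")
  if (delay == 0) return(x)
  m <- stats::nextn(n + ceiling(delay * fs) + 1L, c(2L, 3L, 5L))
  H <- delay_transfer(m, fs, rep(delay, m))
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) * H, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Propagate a signal through a dispersive tissue
#'
#' Each frequency bin travels at its own phase velocity: the transfer
#' function is `exp(-i 2 pi f d / v(f))` with `v(f)` from
#' [phase_velocity()]. Phase-only (unit gain) — amplitude transmittance is
#' deliberately not modelled. The zero-frequency bin passes unchanged.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency, Hz.
#' @param distance Propagation distance in metres, > 0.
#' @param spectrum A [permittivity_spectrum()].
#' @return Propagated signal, same length as `x`.
#' @export
propagate_dispersive <- function(x, fs, distance, spectrum) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stop("distance must be a single positive number")
  n <- length(x)
  if (n == 0L) stop("empty signal")
  v_min <- speed_of_light /
    refractive_index(max(spectrum$eps_r), spectrum$mu_r)
  pad <- ceiling(distance / v_min * fs) + 1L
  m <- stats::nextn(n + pad, c(2L, 3L, 5L))
  f <- freq_bins(m, fs)
  tau <- numeric(m)
  nz <- f != 0
  tau[nz] <- distance / phase_velocity(abs(f[nz]), spectrum)
  H <- delay_transfer(m, fs, tau)
  H[1L] <- 1
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) * H, inverse = TRUE)) / m
  y[seq_len(n)]
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Add white Gaussian noise at a target SNR
#'
#' Scales zero-mean Gaussian noise so that
#' \eqn{10\log_{10}(P_\mathrm{signal}/P_\mathrm{noise})} equals `snr_db`,
#' with powers taken as mean squares over the full record. `snr_db = Inf`
#' is the no-noise sentinel and returns the input unchanged.
#'
#' @param x Numeric signal, not all zero.
#' @param snr_db Target signal-to-noise ratio in dB (the study's recordings
#'   sit near 12.45 dB).
#' @param seed Integer seed; the same seed reproduces the same noise.
#' @return `x` plus noise.
#' @export
add_white_noise <- function(x, snr_db, seed) {
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  p_sig <- mean(x^2)
  if (p_sig == 0) stop("all-zero signal: SNR is undefined")
  noise <- with_seed(seed, stats::rnorm(length(x)))
  # scale the realisation to the exact empirical power, not just in expectation
  noise <- noise * sqrt(p_sig / 10^(snr_db / 10) / mean(noise^2))
  x + noise
}

#' Add (optionally gated) power-line interference
#'
#' Adds `amplitude * sin(2 pi freq t) * envelope(t)`. With a gate mask the
#' envelope is 1 inside the mask and 0 outside, emulating the
#' multiplicative-looking mains residual that appears only within the QRS
#' complex; without a gate the tone is continuous.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency, Hz.
#' @param freq Interference frequency in Hz, below Nyquist (mains residuals
#'   near 50-54 Hz are typical).
#' @param amplitude Tone amplitude in mV.
#' @param gate Optional logical/0-1 mask of the same length as `x`.
#' @return `x` plus the gated tone.
#' @export
add_powerline <- function(x, fs, freq = 54, amplitude = 0.05, gate = NULL) {
  if (freq <= 0 || freq >= fs / 2)
    stop("freq must lie strictly between 0 and the Nyquist frequency")
  if (amplitude == 0) return(x)
  n <- length(x)
  env <- if (is.null(gate)) 1 else {
    if (length(gate) != n) stop("gate mask must match the signal length")
    as.numeric(gate != 0)
  }
  t <- (seq_len(n) - 1) / fs
  x + amplitude * sin(2 * pi * freq * t) * env
}

#' Mask of samples within a QRS support window around each R peak
#'
#' @param n Record length in samples.
#' @param fs Sampling frequency, Hz.
#' @param qrs_times R-peak times in seconds.
#' @param half_width_s Half-width of the window around each peak, seconds.
#' @return Logical vector of length `n`.
#' @export
qrs_mask <- function(n, fs, qrs_times, half_width_s = 0.06) {
  mask <- logical(n)
  for (tc in qrs_times) {
    i0 <- max(1L, floor((tc - half_width_s) * fs) + 1L)
    i1 <- min(n, ceiling((tc + half_width_s) * fs) + 1L)
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  mask
}

#' Two-channel biopotential recording
#'
#' Paired equal-length sampled channels plus the acquisition metadata the
#' velocity estimate needs: sampling rate and electrode separation. Channel 1
#' is the proximal (collar-bone) electrode, channel 2 the distal (wrist)
#' electrode; a positive inter-channel delay means channel 2 lags channel 1.
#'
#' @param ch1,ch2 Numeric sample vectors in mV, equal length.
#' @param fs Sampling frequency in Hz, > 0.
#' @param distance Electrode separation in metres, > 0.
#' @param subject_id Free-text identifier.
#' @return An object of class `two_channel_recording`.
#' @export
two_channel_recording <- function(ch1, ch2, fs, distance,
                                  subject_id = "anonymous") {
  if (length(ch1) != length(ch2)) stop("channels must have equal length")
  if (length(ch1) == 0L) stop("empty recording")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (!is.numeric(distance) || distance <= 0) stop("distance must be positive")
  structure(list(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2), fs = fs,
                 distance = distance, subject_id = as.character(subject_id)),
            class = "two_channel_recording")
}

#' @export
print.two_channel_recording <- function(x, ...) {
  cat(sprintf(
    "<two_channel_recording> subject %s: %d samples/channel @ %g Hz (%.3g s), d = %g m\n",
    x$subject_id, length(x$ch1), x$fs, length(x$ch1) / x$fs, x$distance))
  invisible(x)
}

#' Simulate a two-channel recording with known ground truth
#'
#' End-to-end emulation of the collar-bone/wrist experiment: a rendered ECG
#' forms the proximal channel, a delayed copy (constant velocity or full
#' dispersive propagation) the distal channel, and each channel receives an
#' independent white-noise stream derived from `seed`. Optional gated
#' power-line interference is added to both channels.
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency, Hz.
#' @param n_beats Number of beats.
#' @param distance Electrode separation in metres.
#' @param velocity Constant propagation velocity in m/s, or `NULL` to use
#'   `spectrum`.
#' @param spectrum A [permittivity_spectrum()] for dispersive propagation
#'   (ignored when `velocity` is given).
#' @param snr_db Per-channel SNR in dB; `Inf` for noiseless.
#' @param powerline `NULL`, or a list with elements `freq` (Hz), `amplitude`
#'   (mV) and optional `gated` (logical, default TRUE: restrict the tone to
#'   the QRS support).
#' @param seed Integer master seed; sub-seeds for the two noise streams are
#'   derived from it, so the whole recording is bit-reproducible.
#' @param subject_id Identifier stored in the recording.
#' @return A list with elements `recording` (a [two_channel_recording()]) and
#'   `truth` (list: `true_delay_s`, `true_velocity`, `qrs_times`).
#' @export
simulate_recording <- function(template, fs, n_beats, distance,
                               velocity = NULL, spectrum = NULL,
                               snr_db = 12.45, powerline = NULL, seed = 1L,
                               subject_id = "synthetic") {
  clean <- render_ecg(template, fs, n_beats)
  if (!is.null(velocity)) {
    if (velocity <= 0) stop("velocity must be positive")
    true_delay <- distance / velocity
    ch2 <- propagate_constant(clean, fs, true_delay)
    true_velocity <- velocity
  } else {
    if (is.null(spectrum)) stop("supply either velocity or spectrum")
    ch2 <- propagate_dispersive(clean, fs, distance, spectrum)
    # dominant ECG power sits near 10 Hz; quote the delay there
    true_delay <- theoretical_delay(distance, 10, spectrum)
    true_velocity <- distance / true_delay
  }
  qrs <- r_peak_times(template, n_beats)
  ch1 <- clean
  if (!is.null(powerline)) {
    gate <- if (isFALSE(powerline$gated)) NULL
            else qrs_mask(length(clean), fs, qrs)
    ch1 <- add_powerline(ch1, fs, powerline$freq, powerline$amplitude, gate)
    ch2 <- add_powerline(ch2, fs, powerline$freq, powerline$amplitude, gate)
  }
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  ch1 <- add_white_noise(ch1, snr_db, sub[[1L]])
  ch2 <- add_white_noise(ch2, snr_db, sub[[2L]])
  list(
    recording = two_channel_recording(ch1, ch2, fs, distance, subject_id),
    truth = list(true_delay_s = true_delay, true_velocity = true_velocity,
                 qrs_times = qrs)
  )
}
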