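#' Construct a correlation function object
#'
#' Holds the cross-correlation values over a contiguous integer lag axis.
#' The sign convention throughout the package: a peak at positive lag `k`
#' means channel 2 is delayed `k` samples relative to channel 1 (the distal
#' electrode sees the wave later).
#'
#' @param lags Integer lag axis, contiguous.
#' @param values Correlation value at each lag.
#' @param norm Energy normaliser `sqrt(sum(ch1^2) * sum(ch2^2))`, used to
#'   express the peak on a scale-free [0, 1] scale.
#' @param method `"fft"` or `"direct"`.
#' @return An object of class `correlation_function`.
#' @export
correlation_function <- function(lags, values, norm = NA_real_,
                                 method = "fft") {
  if (length(lags) != length(values)) stop("lags and values differ in length")
  if (length(lags) == 0L) stop("empty correlation function")
  if (length(lags) > 1L && any(diff(lags) != 1L))
    stop("lags must be contiguous integers")
  structure(list(lags = as.integer(lags), values = as.numeric(values),
                 norm = norm, method = method),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("<correlation_function> lags %d..%d (%s method)\n",
              min(x$lags), max(x$lags), x$method))
  invisible(x)
}

#' Cross-correlation via the fast Fourier transform
#'
#' Full linear cross-correlation
#' \eqn{c(k) = \sum_n \mathrm{ch1}[n]\,\mathrm{ch2}[n+k]} computed by
#' frequency-domain multiplication with zero-padding (to a 2-3-5 smooth
#' length) so no circular artefact can contaminate the peak. This is the
#' production path: at the megasample record lengths this measurement needs,
#' the direct sum is orders of magnitude too slow.
#'
#' @param ch1 Proximal-channel samples (non-empty).
#' @param ch2 Distal-channel samples (non-empty).
#' @return A [correlation_function()] over lags
#'   `-(length(ch1)-1) .. (length(ch2)-1)`.
#' @export
cross_correlate_fft <- function(ch1, ch2) {
  n1 <- length(ch1); n2 <- length(ch2)
  if (n1 == 0L || n2 == 0L) stop("empty input channel")
  m <- stats::nextn(n1 + n2 - 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(ch1, numeric(m - n1)))
  Y <- stats::fft(c(ch2, numeric(m - n2)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  lags <- -(n1 - 1L):(n2 - 1L)
  correlation_function(lags, cc[(lags %% m) + 1L],
                       norm = sqrt(sum(ch1^2) * sum(ch2^2)),
                       method = "fft")
}

#' Cross-correlation from the defining sum
#'
#' Evaluates \eqn{c(k) = \sum_n \mathrm{ch1}[n]\,\mathrm{ch2}[n+k]} directly
#' at every lag. O(n^2): intended for short records and as the independent
#' oracle against which the FFT path is verified.
#'
#' @inheritParams cross_correlate_fft
#' @return A [correlation_function()], same axis and convention as
#'   [cross_correlate_fft()].
#' @export
cross_correlate_direct <- function(ch1, ch2) {
  n1 <- length(ch1); n2 <- length(ch2)
  if (n1 == 0L || n2 == 0L) stop("empty input channel")
  lags <- -(n1 - 1L):(n2 - 1L)
  vals <- vapply(lags, function(k) {
    n <- seq_len(n1)
    j <- n + k
    ok <- j >= 1L & j <= n2
    sum(ch1[ok] * ch2[j[ok]])
  }, numeric(1))
  correlation_function(lags, vals,
                       norm = sqrt(sum(ch1^2) * sum(ch2^2)),
                       method = "direct")
}

#' Restrict a correlation function to a lag window
#'
#' The peak search is limited to the order of magnitude the tissue model
#' predicts: by default delays between `distance / v_ceiling` (30,000 m/s,
#' the 10 Hz muscle ceiling) and `distance / v_floor` (100 m/s). This
#' suppresses the trivial zero-lag noise peak and the beat-period ambiguity
#' peaks at multiples of the RR interval.
#'
#' @param corr A [correlation_function()].
#' @param min_lag,max_lag Window bounds in samples, `min_lag < max_lag`.
#' @return The windowed [correlation_function()].
#' @export
restrict_lags <- function(corr, min_lag, max_lag) {
  stopifnot(inherits(corr, "correlation_function"))
  if (min_lag >= max_lag) stop("min_lag must be below max_lag")
  keep <- corr$lags >= min_lag & corr$lags <= max_lag
  if (!any(keep)) stop("lag window is empty")
  correlation_function(corr$lags[keep], corr$values[keep],
                       norm = corr$norm, method = corr$method)
}

# theory window in samples for a given distance / fs
theory_lag_window <- function(distance, fs, v_floor = 100, v_ceiling = 30000) {
  c(max(1L, floor(distance / v_ceiling * fs)),
    ceiling(distance / v_floor * fs))
}

#' A lag estimate and its time conversion
#'
#' @param lag_samples Lag in samples (fractional when sub-sample refinement
#'   is enabled).
#' @param fs Sampling frequency in Hz; `NA` leaves the time fields `NA`.
#' @param peak_corr Normalised peak correlation in [-1, 1].
#' @param method `"fft"` or `"direct"`.
#' @return Object of class `lag_estimate` with `lag_samples`,
#'   `sampling_time_s` (= 1/fs), `delay_s` (= lag * sampling time),
#'   `peak_corr`, `method`.
#' @export
lag_estimate <- function(lag_samples, fs = NA_real_, peak_corr = NA_real_,
                         method = "fft") {
  ts <- 1 / fs
  structure(list(lag_samples = lag_samples, sampling_time_s = ts,
                 delay_s = lag_samples * ts, peak_corr = peak_corr,
                 method = method),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf(
    "<lag_estimate> lag = %s samples, Ts = %s s, T = %s s, peak_corr = %s\n",
    format(x$lag_samples), format(x$sampling_time_s), format(x$delay_s),
    format(x$peak_corr)))
  invisible(x)
}

#' Locate the correlation peak
#'
#' Returns the lag of the maximum correlation value. Ties are broken toward
#' the smallest `|lag|`, then toward the positive lag — deterministic and
#' conservative (it biases toward the faster, theory-consistent velocity).
#' With `subsample = TRUE` the integer peak is refined by parabolic
#' interpolation through the three points around it.
#'
#' @param corr A [correlation_function()].
#' @param fs Sampling frequency, Hz, to convert the lag into a delay;
#'   `NA` keeps the estimate in samples only.
#' @param subsample Enable parabolic sub-sample refinement (off by default:
#'   integer-sample lags match how the measurement is reported).
#' @return A [lag_estimate()].
#' @export
peak_lag <- function(corr, fs = NA_real_, subsample = FALSE) {
  stopifnot(inherits(corr, "correlation_function"))
  v <- corr$values
  mx <- max(v)
  if (mx == min(v) && length(v) > 1L)
    stop("no unique peak: all correlation values are equal")
  cand <- corr$lags[v == mx]
  lag <- cand[order(abs(cand), -cand)][[1L]]
  lag_f <- as.numeric(lag)
  if (subsample) {
    i <- match(lag, corr$lags)
    if (i > 1L && i < length(v)) {
      a <- v[i - 1L]; b <- v[i]; cc <- v[i + 1L]
      den <- a - 2 * b + cc
      if (den < 0) lag_f <- lag + 0.5 * (a - cc) / den
    }
  }
  pc <- if (is.na(corr$norm) || corr$norm == 0) NA_real_ else mx / corr$norm
  lag_estimate(lag_f, fs = fs, peak_corr = pc, method = corr$method)
}

#' Velocity from a lag estimate (v = d / T)
#'
#' Converts a positive inter-channel delay into a propagation velocity.
#' `delay_rounding` reproduces display-precision arithmetic: the delay is
#' rounded to that quantum (in seconds) before dividing, e.g.
#' `delay_rounding = 1e-5` rounds T to hundredths of a millisecond, the
#' precision at which such delays are conventionally quoted.
#'
#' @param lag A [lag_estimate()] with a positive delay.
#' @param distance Electrode separation in metres, > 0.
#' @param delay_rounding Optional rounding quantum for the delay, seconds.
#' @param quality Optional [assess_quality()] report to attach.
#' @return Object of class `velocity_measurement`: `velocity` (m/s),
#'   `distance`, `lag`, `quality`.
#' @export
lag_to_velocity <- function(lag, distance, delay_rounding = NULL,
                            quality = NULL) {
  stopifnot(inherits(lag, "lag_estimate"))
  if (!is.numeric(distance) || distance <= 0) stop("distance must be positive")
  delay <- lag$delay_s
  if (is.na(delay)) stop("lag estimate carries no sampling rate")
  if (delay <= 0)
    stop("non-physical lag: the distal channel leads the proximal one")
  if (!is.null(delay_rounding))
    delay <- round(delay / delay_rounding) * delay_rounding
  structure(list(velocity = distance / delay, distance = distance,
                 lag = lag, quality = quality),
            class = "velocity_measurement")
}

#' @export
print.velocity_measurement <- function(x, ...) {
  cat(sprintf("<velocity_measurement> v = %s m/s over d = %g m (lag %s samples)\n",
              format(signif(x$velocity, 6)), x$distance,
              format(x$lag$lag_samples)))
  if (!is.null(x$quality)) print(x$quality)
  invisible(x)
}

#' Run the full velocity measurement on one recording
#'
#' The complete estimation chain: optional software filtering, FFT
#' cross-correlation of the two channels, restriction of the peak search to
#' the theory-bounded lag window, peak location, conversion to velocity,
#' and quality gating. A rejected measurement is still returned (with
#' `quality$accepted = FALSE` and `velocity = NA` when the lag is
#' non-physical) so rejection counts can be reported.
#'
#' @param recording A [two_channel_recording()].
#' @param config A [run_config()]; `fs` and `distance` are taken from the
#'   recording.
#' @return A `velocity_measurement` whose `diagnostics` element retains the
#'   lag window, SNR, and the correlation values around the peak.
#' @export
run_measurement <- function(recording, config = run_config()) {
  stopifnot(inherits(recording, "two_channel_recording"))
  fs <- recording$fs
  d <- recording$distance
  ch1 <- recording$ch1
  ch2 <- recording$ch2
  if (isTRUE(config$band_enabled)) {
    ch1 <- apply_filters(ch1, fs, band = config$band, notch = NULL)
    ch2 <- apply_filters(ch2, fs, band = config$band, notch = NULL)
  }
  if (isTRUE(config$notch_enabled)) {
    ch1 <- apply_filters(ch1, fs, band = NULL, notch = config$notch)
    ch2 <- apply_filters(ch2, fs, band = NULL, notch = config$notch)
  }
  w <- theory_lag_window(d, fs, config$v_floor, config$v_ceiling)
  corr <- cross_correlate_fft(ch1, ch2)
  # search the symmetric magnitude window so a distal-channel-leading
  # recording surfaces as a flagged negative lag instead of vanishing
  windowed <- restrict_lags(corr, -w[[2L]], w[[2L]])
  lag <- peak_lag(windowed, fs = fs, subsample = isTRUE(config$subsample))
  win_s <- min(length(ch1), config$filter_window)
  if (win_s %% 2L == 0L) win_s <- win_s - 1L
  snr <- estimate_snr_db(ch1, win_s)
  quality <- assess_quality(recording, lag,
                            min_peak_corr = config$min_peak_corr,
                            physical_window = d / c(config$v_ceiling,
                                                    config$v_floor),
                            snr_db = snr)
  vel <- if (lag$delay_s > 0) d / lag$delay_s else NA_real_
  keep <- which(abs(windowed$lags - round(lag$lag_samples)) <= 50L)
  out <- structure(list(velocity = vel, distance = d, lag = lag,
                        quality = quality),
                   class = "velocity_measurement")
  out$diagnostics <- list(
    lag_window = w, snr_db = snr, subject_id = recording$subject_id,
    peak_neighbourhood = list(lags = windowed$lags[keep],
                              values = windowed$values[keep]))
  out
}
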