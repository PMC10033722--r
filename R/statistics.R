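#' Summary statistics over accepted velocity measurements
#'
#' Aggregates a set of [run_measurement()] / [lag_to_velocity()] results
#' into the per-subject summary: count of accepted measurements, mean,
#' sample (n-1) standard deviation, median, and relative uncertainty
#' (100 * sd / mean, in percent). Measurements whose quality report is
#' rejected, or whose velocity is `NA`, are excluded from all statistics;
#' their count is reported separately.
#'
#' @param measurements A list of `velocity_measurement` objects, or a plain
#'   numeric vector of velocities (all treated as accepted).
#' @return Object of class `velocity_stats`: `n`, `n_collected`,
#'   `n_rejected`, `mean`, `sd`, `median`, `relative_uncertainty`
#'   (full precision; use [relative_uncertainty()] for the integer-percent
#'   display form).
#' @export
aggregate_velocities <- function(measurements) {
  if (inherits(measurements, "velocity_measurement"))
    measurements <- list(measurements)
  if (is.numeric(measurements)) {
    v <- measurements
    n_total <- length(v)
  } else {
    n_total <- length(measurements)
    acc <- vapply(measurements, function(m) {
      is.null(m$quality) || isTRUE(m$quality$accepted)
    }, logical(1))
    v <- vapply(measurements[acc], function(m) m$velocity, numeric(1))
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no accepted measurements")
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  structure(list(
    n = length(v), n_collected = n_total, n_rejected = n_total - length(v),
    mean = m, sd = s, median = stats::median(v),
    relative_uncertainty = 100 * s / m),
    class = "velocity_stats")
}

#' @export
print.velocity_stats <- function(x, ...) {
  # Table-style display: two significant figures, full precision retained
  cat(sprintf(
    "<velocity_stats> n = %d accepted of %d: mean %s m/s, sd %s m/s, median %s m/s (rel. uncertainty %d%%)\n",
    x$n, x$n_collected, format(signif(x$mean, 2)), format(signif(x$sd, 2)),
    format(signif(x$median, 2)), round(x$relative_uncertainty)))
  invisible(x)
}

#' Relative uncertainty of a velocity distribution
#'
#' `100 * sd / mean`, rounded to the nearest integer percent for reporting
#' (e.g. mean 1800 m/s with sd 600 m/s gives 33%).
#'
#' @param mean Mean velocity, > 0.
#' @param sd Standard deviation, >= 0.
#' @param digits Rounding digits for the percentage (0 = integer percent).
#' @return Relative uncertainty in percent.
#' @export
relative_uncertainty <- function(mean, sd, digits = 0) {
  if (!is.numeric(mean) || any(mean <= 0)) stop("mean must be positive")
  round(100 * sd / mean, digits)
}

#' Diagnose a periodic distortion from residual peak spacing
#'
#' Finds the prominent local maxima of a residual trace (the same
#' fractional-threshold rule used for QRS triggering) and converts their
#' mean spacing into a period and frequency. An 18.5 ms spacing diagnoses a
#' 54 Hz mains residual.
#'
#' @param residual Residual signal (e.g. raw minus smoothed).
#' @param fs Sampling frequency, Hz.
#' @param prominence_frac Fraction of the global maximum a peak must reach.
#' @return Object of class `distortion_diagnostic`: `period_s`,
#'   `frequency_hz` (= 1/period), `n_peaks`.
#' @export
distortion_frequency <- function(residual, fs, prominence_frac = 0.5) {
  pk <- local_maxima(residual)
  pk <- pk[residual[pk] >= prominence_frac * max(residual)]
  if (length(pk) < 3L)
    stop("insufficient peaks: need at least 3 to estimate a period")
  period <- mean(diff(pk)) / fs
  structure(list(period_s = period, frequency_hz = 1 / period,
                 n_peaks = length(pk)),
            class = "distortion_diagnostic")
}

#' @export
print.distortion_diagnostic <- function(x, ...) {
  cat(sprintf(
    "<distortion_diagnostic> period %.4g ms -> %g Hz (%d peaks)\n",
    1000 * x$period_s, round(x$frequency_hz), x$n_peaks))
  invisible(x)
}

#' Ratio of two velocities
#'
#' Contextualises the field propagation velocity against a reference such as
#' the ~4 m/s activation conduction velocity of Purkinje fibres (1500 / 4 =
#' 375).
#'
#' @param v Velocity, m/s.
#' @param v_ref Reference velocity, m/s, > 0.
#' @return Dimensionless ratio `v / v_ref`.
#' @export
velocity_ratio <- function(v, v_ref) {
  if (!is.numeric(v_ref) || any(v_ref <= 0)) stop("reference velocity must be positive")
  v / v_ref
}

#' Per-subject summary table of velocity statistics
#'
#' @param stats_list Named list of `velocity_stats` (names = subject ids).
#' @param path Optional path; when given the table is written as
#'   tab-delimited text.
#' @return A data.frame with columns subject, n, mean, sd, median,
#'   relative_uncertainty (percent, integer).
#' @export
summary_table <- function(stats_list, path = NULL) {
  stopifnot(length(stats_list) >= 1L)
  df <- data.frame(
    subject = names(stats_list),
    n = vapply(stats_list, `[[`, numeric(1), "n"),
    mean = vapply(stats_list, `[[`, numeric(1), "mean"),
    sd = vapply(stats_list, `[[`, numeric(1), "sd"),
    median = vapply(stats_list, `[[`, numeric(1), "median"),
    relative_uncertainty = vapply(stats_list, function(s)
      relative_uncertainty(s$mean, s$sd), numeric(1)),
    row.names = NULL)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
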