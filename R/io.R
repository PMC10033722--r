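#' Write a two-channel recording to delimited text
#'
#' Tab-separated columns `time_s`, `ch1_mV`, `ch2_mV`, preceded by
#' `#`-prefixed header lines carrying the sampling rate, electrode distance,
#' subject id and (when supplied) the simulation seed and ground truth. A
#' YAML sidecar `<path>.meta.yml` duplicates the metadata in key-value form.
#'
#' @param recording A [two_channel_recording()].
#' @param path Output file path.
#' @param truth Optional ground-truth list from [simulate_recording()].
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, truth = NULL, seed = NULL) {
  stopifnot(inherits(recording, "two_channel_recording"))
  meta <- list(fs_hz = recording$fs, distance_m = recording$distance,
               subject_id = recording$subject_id)
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(truth)) {
    meta$true_delay_s <- truth$true_delay_s
    meta$true_velocity_m_s <- truth$true_velocity
  }
  hdr <- c("# ecgvelocity two-channel recording",
           vapply(names(meta), function(k)
             sprintf("# %s: %s", k, format(meta[[k]], digits = 17)),
             character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\tch1_mV\tch2_mV", con)
  t <- (seq_along(recording$ch1) - 1) / recording$fs
  utils::write.table(
    data.frame(t, recording$ch1, recording$ch2), con, sep = "\t",
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

parse_header_meta <- function(lines) {
  kv <- grep("^#\\s*[A-Za-z_][A-Za-z0-9_]*\\s*:", lines, value = TRUE)
  out <- list()
  for (l in kv) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", l))[[1L]]
    val <- trimws(m[[3L]])
    num <- suppressWarnings(as.numeric(val))
    out[[m[[2L]]]] <- if (is.na(num)) val else num
  }
  out
}

#' Read a two-channel recording from delimited text
#'
#' Accepts either three numeric columns (time + two channels) or two
#' (channels only). The sampling rate is resolved in priority order:
#' `fs_override`, an `fs_hz` key in the `#` header, then the spacing of the
#' time column — which must be uniform to within 1 ppm, otherwise an error
#' asks for an explicit rate.
#'
#' @param path Input file path.
#' @param fs_override Sampling frequency in Hz, overriding all other sources.
#' @param distance_override Electrode distance in m, overriding the header.
#' @return A [two_channel_recording()] with the header metadata (including
#'   any ground truth) attached as attribute `"meta"`.
#' @export
read_recording <- function(path, fs_override = NULL, distance_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header_meta(lines[grepl("^#", lines)])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data lines in ", path)
  first <- strsplit(trimws(body[[1L]]), "[\\t, ]+")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) body <- body[-1L]
  tab <- utils::read.table(text = body, sep = "")
  if (ncol(tab) < 2L) stop("expected at least 2 numeric columns")
  has_time <- ncol(tab) >= 3L
  fs <- fs_override
  if (is.null(fs) && !is.null(meta$fs_hz)) fs <- meta$fs_hz
  if (is.null(fs)) {
    if (!has_time)
      stop("sampling rate unavailable: no override, header fs_hz or time column")
    dt <- diff(tab[[1L]])
    if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
      stop("time column spacing jitter exceeds 1 ppm; supply fs_override")
    fs <- 1 / mean(dt)
  }
  distance <- distance_override %||% meta$distance_m %||%
    stop("electrode distance unavailable: supply distance_override or header")
  ch1 <- tab[[if (has_time) 2L else 1L]]
  ch2 <- tab[[if (has_time) 3L else 2L]]
  rec <- two_channel_recording(ch1, ch2, fs, distance,
                               subject_id = meta$subject_id %||% "unknown")
  attr(rec, "meta") <- meta
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measurement_record <- function(m) {
  q <- m$quality
  list(
    subject = m$diagnostics$subject_id %||% NA_character_,
    velocity_m_s = m$velocity,
    distance_m = m$distance,
    lag_samples = m$lag$lag_samples,
    sampling_time_s = m$lag$sampling_time_s,
    delay_s = m$lag$delay_s,
    peak_corr = m$lag$peak_corr,
    snr_db = if (is.null(q)) NA_real_ else q$snr_db,
    accepted = if (is.null(q)) TRUE else q$accepted,
    reject_reason = if (is.null(q) || is.na(q$reject_reason)) NA_character_
                    else q$reject_reason)
}

#' Write a run report as JSON
#'
#' Serialises the configuration echo, every per-recording measurement
#' (full-precision numbers plus display-rounded mirror fields), the summary
#' statistics over accepted measurements, the package version and a
#' timestamp. When no measurement was accepted, the `stats` section is
#' marked absent rather than fabricated. `read_report()` restores the
#' document; write-then-read round-trips.
#'
#' @param measurements List of `velocity_measurement` objects (non-empty).
#' @param path Output path.
#' @param config Optional [run_config()] to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(measurements, path, config = NULL) {
  if (inherits(measurements, "velocity_measurement"))
    measurements <- list(measurements)
  if (length(measurements) == 0L) stop("empty measurement list")
  recs <- lapply(measurements, measurement_record)
  stats <- tryCatch(aggregate_velocities(measurements), error = function(e) NULL)
  report <- list(
    software = list(package = "ecgvelocity",
                    version = as.character(utils::packageVersion("ecgvelocity"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else unclass(config),
    measurements = recs,
    stats = if (is.null(stats)) NULL else {
      s <- unclass(stats)
      s$display <- list(mean = signif(stats$mean, 2), sd = signif(stats$sd, 2),
                        median = signif(stats$median, 2),
                        relative_uncertainty_pct = round(stats$relative_uncertainty))
      s
    },
    stats_absent = is.null(stats))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
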