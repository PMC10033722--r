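#' Pipeline run configuration
#'
#' All tunables of the estimation pipeline with validated defaults. The
#' defaults mirror the acquisition the package emulates: a 5001-sample
#' smoothing window, a 0.1-200 Hz analogue band and a 50 Hz notch (both off
#' in software by default), a lag window bounded by the 30,000 m/s
#' theoretical ceiling and a 100 m/s floor, a 0.7 peak-correlation
#' acceptance threshold and a 12.45 dB simulation SNR.
#'
#' @param fs Sampling frequency, Hz (NULL: take it from each recording).
#' @param distance Electrode distance, m (NULL: from each recording).
#' @param filter_window Rolling-mean window, odd samples.
#' @param band Band-pass edges, Hz.
#' @param band_enabled Apply the software band-pass.
#' @param notch Notch frequency, Hz.
#' @param notch_enabled Apply the software notch.
#' @param v_floor Lowest admissible velocity, m/s.
#' @param v_ceiling Highest admissible velocity (theory bound), m/s.
#' @param min_peak_corr Acceptance threshold on normalised peak correlation.
#' @param snr_db Simulation signal-to-noise ratio, dB.
#' @param subsample Parabolic sub-sample lag refinement.
#' @param trigger_threshold_frac Slope-threshold fraction for triggering.
#' @param refractory_s Trigger refractory period, s.
#' @param seed Integer seed for simulations.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fs = NULL, distance = NULL, filter_window = 5001L,
                       band = c(0.1, 200), band_enabled = FALSE,
                       notch = 50, notch_enabled = FALSE,
                       v_floor = 100, v_ceiling = 30000,
                       min_peak_corr = 0.7, snr_db = 12.45,
                       subsample = FALSE, trigger_threshold_frac = 0.5,
                       refractory_s = 0.3, seed = NULL) {
  cfg <- list(fs = fs, distance = distance,
              filter_window = as.integer(filter_window),
              band = as.numeric(band), band_enabled = isTRUE(band_enabled),
              notch = as.numeric(notch), notch_enabled = isTRUE(notch_enabled),
              v_floor = as.numeric(v_floor), v_ceiling = as.numeric(v_ceiling),
              min_peak_corr = as.numeric(min_peak_corr),
              snr_db = as.numeric(snr_db), subsample = isTRUE(subsample),
              trigger_threshold_frac = as.numeric(trigger_threshold_frac),
              refractory_s = as.numeric(refractory_s),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  known <- c("fs", "distance", "filter_window", "band", "band_enabled",
             "notch", "notch_enabled", "v_floor", "v_ceiling",
             "min_peak_corr", "snr_db", "subsample",
             "trigger_threshold_frac", "refractory_s", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(cfg$fs) && cfg$fs <= 0) stop("fs must be positive")
  if (!is.null(cfg$distance) && cfg$distance <= 0)
    stop("distance must be positive")
  if (cfg$filter_window < 1 || cfg$filter_window %% 2 == 0)
    stop("filter_window must be odd and >= 1")
  if (length(cfg$band) != 2 || any(cfg$band <= 0) || cfg$band[1] >= cfg$band[2])
    stop("band must be two increasing positive frequencies")
  if (cfg$v_floor <= 0 || cfg$v_ceiling <= cfg$v_floor)
    stop("need 0 < v_floor < v_ceiling")
  if (cfg$min_peak_corr < 0 || cfg$min_peak_corr > 1)
    stop("min_peak_corr must lie in [0, 1]")
  if (cfg$trigger_threshold_frac <= 0 || cfg$trigger_threshold_frac > 1)
    stop("trigger_threshold_frac must lie in (0, 1]")
  if (cfg$refractory_s < 0) stop("refractory_s must be non-negative")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(v)) "(from recording)" else paste(v, collapse = " ")))
  }
  invisible(x)
}

#' Load / save a run configuration (YAML key-value file)
#'
#' Unknown keys are rejected with a message naming them; every known key is
#' validated. `save_config()` followed by `load_config()` round-trips.
#'
#' @param path File path.
#' @return `load_config()`: a [run_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a key-value mapping")
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname load_config
#' @param config A [run_config()].
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
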