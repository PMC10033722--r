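# shared fixtures: tiny spectra, templates and band-limited random signals

muscle_point <- function() permittivity_spectrum(10, 1e8)

two_point_spectrum <- function(extrapolation = "clamp")
  permittivity_spectrum(c(10, 1000), c(1e8, 1e6), extrapolation = extrapolation)

r_only_template <- function(rr = 1)
  beat_template(amplitude_mv = c(P = 0, Q = 0, R = 1, S = 0, T = 0),
                rr_interval_s = rr)

# smooth (band-limited) random signal: white noise convolved with a Gaussian
# kernel, so correlation peaks are unambiguous
smooth_noise <- function(n, seed, sigma_samples = 8) {
  set.seed(seed)
  x <- stats::rnorm(n + 8 * sigma_samples)
  k <- stats::dnorm(seq(-4 * sigma_samples, 4 * sigma_samples), sd = sigma_samples)
  y <- stats::filter(x, k / sum(k), sides = 2)
  as.numeric(y[!is.na(y)])[seq_len(n)]
}

# shift a signal right by k samples, zero-filling (exact integer delay)
shift_int <- function(x, k) c(numeric(k), x)[seq_along(x)]
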