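#' Speed of light used throughout the package
#'
#' Fixed at \eqn{3 \times 10^8} m/s (the rounded value conventional in this
#' measurement context) rather than the exact SI value, so that derived
#' round numbers such as the 30,000 m/s muscle-tissue ceiling reproduce
#' exactly.
#'
#' @format A length-one numeric, in m/s.
#' @export
speed_of_light <- 3e8

#' Relative permittivity spectrum of a tissue
#'
#' Represents the dispersion curve \eqn{\varepsilon_r(f)} of a (linear,
#' isotropic, loss-free) tissue as an ordered table of
#' (frequency, relative permittivity) points. Between tabulated points the
#' spectrum is interpolated linearly in log(f)-log(eps_r) coordinates, the
#' natural axes for tissue dispersion data which spans many decades. Below
#' the lowest tabulated frequency the behaviour is governed by
#' `extrapolation`: `"clamp"` (default) holds the lowest-frequency value,
#' `"powerlaw"` extends the log-log slope of the two lowest points. Above
#' the highest tabulated frequency the value is always clamped.
#'
#' @param frequency_hz Numeric vector of frequencies in Hz, strictly
#'   increasing, all positive.
#' @param eps_r Relative permittivity at each frequency; dimensionless,
#'   all >= 1.
#' @param mu_r Relative magnetic permeability, a single positive number.
#'   Default 1: for muscle tissue it is indistinguishable from unity.
#' @param extrapolation Policy below the tabulated range: `"clamp"` or
#'   `"powerlaw"`.
#' @return An object of class `permittivity_spectrum`.
#' @examples
#' muscle <- permittivity_spectrum(10, 1e8)
#' phase_velocity(10, muscle) # 30,000 m/s
#' @export
permittivity_spectrum <- function(frequency_hz, eps_r, mu_r = 1,
                                  extrapolation = c("clamp", "powerlaw")) {
  extrapolation <- match.arg(extrapolation)
  frequency_hz <- as.numeric(frequency_hz)
  eps_r <- as.numeric(eps_r)
  if (length(frequency_hz) == 0L || length(frequency_hz) != length(eps_r))
    stop("frequency_hz and eps_r must be non-empty vectors of equal length")
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0))
    stop("frequencies must be positive and finite")
  if (is.unsorted(frequency_hz, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (any(!is.finite(eps_r)) || any(eps_r < 1))
    stop("all eps_r values must be finite and >= 1")
  if (!is.numeric(mu_r) || length(mu_r) != 1L || !is.finite(mu_r) || mu_r <= 0)
    stop("mu_r must be a single positive number")
  structure(
    list(frequency_hz = frequency_hz, eps_r = eps_r, mu_r = mu_r,
         extrapolation = extrapolation),
    class = "permittivity_spectrum"
  )
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  cat(sprintf(
    "<permittivity_spectrum> %d point(s), %s-%s Hz, mu_r = %g, extrapolation = %s\n",
    length(x$frequency_hz), format(min(x$frequency_hz)),
    format(max(x$frequency_hz)), x$mu_r, x$extrapolation))
  invisible(x)
}

#' Read a permittivity spectrum from a delimited text file
#'
#' Expects two numeric columns (frequency in Hz, relative permittivity).
#' Lines starting with `#` are ignored; a single non-numeric header line is
#' tolerated.
#'
#' @param path Path to the file.
#' @inheritParams permittivity_spectrum
#' @return A [permittivity_spectrum()].
#' @export
read_permittivity <- function(path, mu_r = 1,
                              extrapolation = c("clamp", "powerlaw")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data lines in ", path)
  first <- strsplit(trimws(lines[[1L]]), "[,;\\s]+")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first)))))
    lines <- lines[-1L] # header line
  tab <- utils::read.table(text = lines, sep = "", comment.char = "#")
  if (ncol(tab) == 1L)
    tab <- utils::read.table(text = lines, sep = ",", comment.char = "#")
  if (ncol(tab) < 2L) stop("expected two columns (frequency_Hz, eps_r) in ", path)
  permittivity_spectrum(tab[[1L]], tab[[2L]], mu_r = mu_r,
                        extrapolation = extrapolation)
}

#' Relative permittivity at a given frequency
#'
#' Evaluates the dispersion curve by log-log interpolation between tabulated
#' points, applying the spectrum's extrapolation policy below the tabulated
#' range (see [permittivity_spectrum()]).
#'
#' @param spectrum A [permittivity_spectrum()].
#' @param f Frequency in Hz, positive (vectorised).
#' @return Relative permittivity value(s), always >= 1.
#' @export
permittivity_at <- function(spectrum, f) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequency must be positive and finite")
  fg <- spectrum$frequency_hz
  eg <- spectrum$eps_r
  n <- length(fg)
  out <- numeric(length(f))
  exact <- match(f, fg) # tabulated frequencies return table values exactly
  hit <- !is.na(exact)
  out[hit] <- eg[exact[hit]]
  below <- !hit & f < fg[1L]
  above <- !hit & f > fg[n]
  out[above] <- eg[n]
  if (any(below)) {
    if (n >= 2L && spectrum$extrapolation == "powerlaw") {
      slope <- (log(eg[2L]) - log(eg[1L])) / (log(fg[2L]) - log(fg[1L]))
      out[below] <- exp(log(eg[1L]) + slope * (log(f[below]) - log(fg[1L])))
    } else {
      out[below] <- eg[1L]
    }
  }
  mid <- !hit & !below & !above
  if (any(mid)) {
    k <- findInterval(f[mid], fg)
    slope <- (log(eg[k + 1L]) - log(eg[k])) / (log(fg[k + 1L]) - log(fg[k]))
    out[mid] <- exp(log(eg[k]) + slope * (log(f[mid]) - log(fg[k])))
  }
  pmax(out, 1)
}

#' Refractive index from permittivity and permeability
#'
#' \eqn{n = \sqrt{\varepsilon_r \mu_r}}.
#'
#' @param eps_r Relative permittivity, >= 1 (vectorised).
#' @param mu_r Relative permeability, > 0.
#' @return Refractive index (dimensionless).
#' @export
refractive_index <- function(eps_r, mu_r = 1) {
  if (any(!is.finite(eps_r)) || any(eps_r < 1))
    stop("eps_r must be >= 1")
  if (any(!is.finite(mu_r)) || any(mu_r <= 0))
    stop("mu_r must be > 0")
  sqrt(eps_r * mu_r)
}

#' Phase velocity of an EM wave in tissue
#'
#' \eqn{v(f) = c / n(f)} with \eqn{n(f) = \sqrt{\varepsilon_r(f)\,\mu_r}}.
#' For muscle tissue at 10 Hz (\eqn{\varepsilon_r = 10^8}) this gives
#' 30,000 m/s, the theoretical ceiling used to bound the lag search window.
#'
#' @param f Frequency in Hz, positive (vectorised).
#' @param spectrum A [permittivity_spectrum()].
#' @return Phase velocity in m/s, never exceeding the speed of light.
#' @export
phase_velocity <- function(f, spectrum) {
  speed_of_light / refractive_index(permittivity_at(spectrum, f),
                                    spectrum$mu_r)
}

#' Theoretical propagation delay across an electrode distance
#'
#' Converts the phase velocity at frequency `f` into a travel time over
#' `distance` metres; used to seed the physically-plausible lag window.
#'
#' @param distance Electrode separation in metres, > 0.
#' @inheritParams phase_velocity
#' @return Delay in seconds.
#' @export
theoretical_delay <- function(distance, f, spectrum) {
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance <= 0))
    stop("distance must be positive")
  distance / phase_velocity(f, spectrum)
}
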