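#' Declare a lossy dielectric material
#'
#' A material is characterised by its (frequency-independent) conductivity
#' \eqn{\sigma} and relative permittivity \eqn{\varepsilon_r}.  At angular
#' frequency \eqn{\omega} it is summarised by the complex permittivity
#' \eqn{\varepsilon^* = \varepsilon_r \varepsilon_0 - i \sigma / \omega}
#' (engineering \eqn{e^{+i\omega t}} convention, so the imaginary part is
#' non-positive for a passive material).
#'
#' @param name label used in region maps and reports.
#' @param sigma conductivity in S/m, must be >= 0 (0 for a perfect
#'   insulator such as a glass cover slip).
#' @param eps_r relative permittivity, must be > 0.
#' @return An object of class `material`.
#' @examples
#' buf <- material("buffer", sigma = 1.5, eps_r = 80)
#' complex_permittivity(buf, 60e3)
#' @export
material <- function(name, sigma, eps_r) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number (S/m)")
  if (!is.numeric(eps_r) || length(eps_r) != 1 || is.na(eps_r) || eps_r <= 0)
    stop("'eps_r' must be a single positive number")
  structure(list(name = name, sigma = sigma, eps_r = eps_r),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: sigma = %g S/m, eps_r = %g\n",
              x$name, x$sigma, x$eps_r))
  invisible(x)
}

#' Complex permittivity of a material
#'
#' Evaluates \eqn{\varepsilon^*(\omega) = \varepsilon_r \varepsilon_0 -
#' i\,\sigma/\omega} with \eqn{\omega = 2\pi f}.
#'
#' @param material a [material()].
#' @param frequency frequency in Hz, strictly positive (vectorised).
#' @return Complex permittivity in F/m, one value per frequency.
#' @export
complex_permittivity <- function(material, frequency) {
  stopifnot(inherits(material, "material"))
  check_frequency(frequency)
  omega <- 2 * pi * frequency
  complex(real = material$eps_r * EPS0, imaginary = -material$sigma / omega)
}

#' Complex admittivity of a material
#'
#' \eqn{\kappa(\omega) = \sigma + i\omega\varepsilon_r\varepsilon_0 =
#' i\omega\varepsilon^*}, the coefficient of the electro-quasistatic
#' current-continuity equation.  Used internally by the FEM assembly and the
#' impedance expressions.
#'
#' @inheritParams complex_permittivity
#' @return Complex admittivity in S/m, one value per frequency.
#' @export
admittivity <- function(material, frequency) {
  stopifnot(inherits(material, "material"))
  check_frequency(frequency)
  omega <- 2 * pi * frequency
  complex(real = material$sigma, imaginary = omega * material$eps_r * EPS0)
}

check_frequency <- function(frequency) {
  if (!is.numeric(frequency) || length(frequency) < 1 ||
      anyNA(frequency) || any(frequency <= 0))
    stop("'frequency' must be positive (Hz)")
  invisible(frequency)
}

#' Logarithmic frequency grid
#'
#' Default sweep grid covering the band accessible to commercial impedance
#' analysers, 10 Hz to 100 MHz.
#'
#' @param n number of points (default 61).
#' @param from,to end points in Hz.
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @export
freq_grid <- function(n = 61, from = 10, to = 1e8) {
  stopifnot(n >= 1, from > 0, to >= from)
  if (n == 1) return(from)
  10^seq(log10(from), log10(to), length.out = n)
}
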