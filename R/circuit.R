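#' A dielectric layer of the stimulation chamber
#'
#' A circular layer of thickness `d` and radius `r`, filled with a single
#' [material()].  Its cross-section is `A = pi * r^2`.
#'
#' @param thickness layer thickness in m.
#' @param radius layer radius in m.
#' @param material a [material()].
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(thickness, radius, material) {
  stopifnot(thickness > 0, inherits(material, "material"))
  if (!(radius > 0)) stop("'radius' must be positive")
  structure(list(d = thickness, r = radius, material = material),
            class = "layer_spec")
}

#' The capacitively coupled stimulation chamber
#'
#' Two glass cover slips (used symmetrically above and below) enclose the
#' cell culture medium; the applied voltage `V0` (amplitude, not RMS) is
#' imposed across the outer cover-slip faces so there is no galvanic contact
#' with the medium.  Defaults are the printed reference geometry:
#' cover slips 0.15 mm thick, radius 16.5 mm, relative permittivity 4;
#' medium 1.415 mm thick, conductivity 1.5 S/m, relative permittivity 80;
#' V0 = 44.81 V.
#'
#' @param cover_slip a [layer_spec()] used for both cover slips.
#' @param buffer a [layer_spec()] for the medium.
#' @param V0 applied voltage amplitude in V, > 0.
#' @return An object of class `chamber_stack`.
#' @export
chamber_stack <- function(cover_slip, buffer, V0 = 44.81) {
  stopifnot(inherits(cover_slip, "layer_spec"),
            inherits(buffer, "layer_spec"))
  if (!(V0 > 0)) stop("'V0' must be positive")
  structure(list(cover_slip = cover_slip, buffer = buffer, V0 = V0),
            class = "chamber_stack")
}

#' @rdname chamber_stack
#' @param sigma_buf,eps_buf medium properties used by the convenience
#'   constructor of the default chamber.
#' @export
default_chamber <- function(sigma_buf = 1.5, eps_buf = 80) {
  chamber_stack(
    cover_slip = layer_spec(0.15e-3, 16.5e-3, material("cs", 0, 4)),
    buffer = layer_spec(1.415e-3, 16.5e-3,
                        material("buf", sigma_buf, eps_buf)),
    V0 = 44.81
  )
}

#' @export
print.chamber_stack <- function(x, ...) {
  cat(sprintf(paste0("<chamber_stack> V0 = %g V\n",
                     "  cover slip: d = %g mm, r = %g mm (%s)\n",
                     "  buffer:     d = %g mm, r = %g mm (%s)\n"),
              x$V0, 1e3 * x$cover_slip$d, 1e3 * x$cover_slip$r,
              x$cover_slip$material$name,
              1e3 * x$buffer$d, 1e3 * x$buffer$r, x$buffer$material$name))
  invisible(x)
}

#' Impedance of a single layer
#'
#' Ideal parallel-plate expression
#' \eqn{Z = 1/(i\omega C) = d / (i\omega \varepsilon^* \pi r^2)}.
#'
#' @param layer a [layer_spec()].
#' @param frequency frequency in Hz (vectorised).
#' @return Complex impedance in ohm per frequency.
#' @export
layer_impedance <- function(layer, frequency) {
  stopifnot(inherits(layer, "layer_spec"))
  check_frequency(frequency)
  A <- pi * layer$r^2
  layer$d / (admittivity(layer$material, frequency) * A)
}

#' Total chamber impedance
#'
#' \eqn{Z_{total} = 2 Z_{cs} + Z_{buf}}: two cover-slip capacitors in series
#' with the lossy medium.
#'
#' @param stack a [chamber_stack()].
#' @param frequency frequency in Hz (vectorised).
#' @return Complex impedance in ohm per frequency.
#' @export
chamber_impedance <- function(stack, frequency) {
  stopifnot(inherits(stack, "chamber_stack"))
  2 * layer_impedance(stack$cover_slip, frequency) +
    layer_impedance(stack$buffer, frequency)
}

#' Voltage across the medium
#'
#' Voltage-divider expression \eqn{V_{buf} = V_0 Z_{buf} / Z_{total}}.
#'
#' @inheritParams chamber_impedance
#' @return Complex voltage amplitude in V per frequency.
#' @export
buffer_voltage <- function(stack, frequency) {
  stopifnot(inherits(stack, "chamber_stack"))
  stack$V0 * layer_impedance(stack$buffer, frequency) /
    chamber_impedance(stack, frequency)
}

#' Electric field in the medium
#'
#' \eqn{E_s = V_{buf}/d_{buf} = (V_0/d_{buf})\, Z_{buf}/Z_{total}}.  The
#' returned value is complex; take `Mod()` for the field amplitude.
#'
#' @inheritParams chamber_impedance
#' @return Complex field amplitude in V/m per frequency.
#' @export
buffer_field <- function(stack, frequency) {
  buffer_voltage(stack, frequency) / stack$buffer$d
}

#' Ohmic power dissipated in the medium
#'
#' Conduction loss \eqn{P = \sigma_{buf} |E_s|^2 \pi r_{buf}^2 d_{buf}}
#' evaluated with the field amplitude (peak, not RMS); an order-of-magnitude
#' check that capacitive-coupling stimulation does not heat the sample.
#'
#' @inheritParams chamber_impedance
#' @return Power in W per frequency.
#' @export
dissipated_power <- function(stack, frequency) {
  stopifnot(inherits(stack, "chamber_stack"))
  Es <- Mod(buffer_field(stack, frequency))
  vol <- pi * stack$buffer$r^2 * stack$buffer$d
  stack$buffer$material$sigma * Es^2 * vol
}

#' Frequency sweep of the equivalent circuit
#'
#' Evaluates impedance, phase, medium voltage and field, and dissipated
#' power on a frequency grid.
#'
#' @param stack a [chamber_stack()].
#' @param grid strictly increasing positive frequency grid in Hz; defaults
#'   to 61 log-spaced points between 10 Hz and 100 MHz.
#' @return A `data.frame` of class `spectrum_result` with columns
#'   `frequency_hz`, `z_abs_ohm`, `z_phase_deg`, `v_buf_v`,
#'   `e_field_v_per_m`, `power_w`.
#' @export
frequency_sweep <- function(stack, grid = freq_grid()) {
  stopifnot(inherits(stack, "chamber_stack"))
  if (length(grid) < 1) stop("frequency grid must be non-empty")
  check_frequency(grid)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("frequency grid must be strictly increasing")
  Z <- chamber_impedance(stack, grid)
  Es <- buffer_field(stack, grid)
  out <- data.frame(
    frequency_hz = grid,
    z_abs_ohm = Mod(Z),
    z_phase_deg = Arg(Z) * 180 / pi,
    v_buf_v = Mod(buffer_voltage(stack, grid)),
    e_field_v_per_m = Mod(Es),
    power_w = dissipated_power(stack, grid)
  )
  class(out) <- c("spectrum_result", "data.frame")
  out
}
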