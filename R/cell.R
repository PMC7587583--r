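#' Cell geometry for single-cell models
#'
#' Describes a eukaryotic cell as a sphere (radius `Rc`) or an oblate
#' ellipsoid (adherent, flattened morphology), with a thin membrane of
#' thickness `dm` and an optional nucleus.  The nucleus radius is expressed
#' through a `scale` parameter, `Rn = scale * Rc`, which keeps the nucleus
#' strictly inside the cell; the nuclear envelope has thickness `dn`.
#'
#' @param shape `"sphere"` or `"oblate_ellipsoid"`.
#' @param Rc cell radius in m (for the ellipsoid, the equivalent radius used
#'   by the spherical dielectric model; the FEM uses `semi_axes`).
#' @param dm membrane thickness in m; must be small compared to `Rc`
#'   (`dm < Rc/100`).
#' @param scale nucleus-to-cell radius ratio in (0, 1); 0 disables the
#'   nucleus.
#' @param dn nuclear envelope thickness in m (ignored when `scale == 0`).
#' @param semi_axes length-2 numeric `(radial, axial)` semi-axes in m, only
#'   used for `"oblate_ellipsoid"`.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(shape = c("sphere", "oblate_ellipsoid"),
                          Rc = 5e-6, dm = 7e-9, scale = 0, dn = 40e-9,
                          semi_axes = NULL) {
  shape <- match.arg(shape)
  stopifnot(Rc > 0, dm > 0, dn >= 0)
  if (dm >= Rc / 100)
    stop("membrane must be thin: dm < Rc/100")
  if (scale < 0 || scale >= 1)
    stop("'scale' must lie in [0, 1)")
  if (scale > 0 && scale * Rc >= Rc - dm)
    stop("nucleus radius scale*Rc must be smaller than Rc - dm")
  if (shape == "oblate_ellipsoid") {
    if (is.null(semi_axes)) semi_axes <- c(10e-6, 2.5e-6)
    stopifnot(length(semi_axes) == 2, all(semi_axes > 0),
              semi_axes[1] >= semi_axes[2])
  }
  structure(list(shape = shape, Rc = Rc, dm = dm, scale = scale,
                 Rn = scale * Rc, dn = dn, semi_axes = semi_axes),
            class = "cell_geometry")
}

#' Per-compartment cell dielectric properties
#'
#' @param membrane,cytoplasm [material()] objects; the membrane conductivity
#'   may be exactly zero.
#' @param nuclear_envelope,nucleoplasm optional [material()] objects; both
#'   must be given for a nucleated cell model.
#' @return An object of class `cell_dielectrics`.
#' @export
cell_dielectrics <- function(membrane, cytoplasm,
                             nuclear_envelope = NULL, nucleoplasm = NULL) {
  stopifnot(inherits(membrane, "material"), inherits(cytoplasm, "material"))
  if (xor(is.null(nuclear_envelope), is.null(nucleoplasm)))
    stop("give both 'nuclear_envelope' and 'nucleoplasm', or neither")
  if (!is.null(nuclear_envelope))
    stopifnot(inherits(nuclear_envelope, "material"),
              inherits(nucleoplasm, "material"))
  structure(list(membrane = membrane, cytoplasm = cytoplasm,
                 nuclear_envelope = nuclear_envelope,
                 nucleoplasm = nucleoplasm),
            class = "cell_dielectrics")
}

#' Equivalent permittivity of a shelled sphere
#'
#' Single-shell reduction: a sphere of radius `outer_radius` made of a core
#' (complex permittivity `inner`) coated by a concentric shell (`shell`,
#' thickness `shell_thickness`) behaves, seen from outside, like a
#' homogeneous sphere with permittivity
#' \deqn{\varepsilon_{eq} = \varepsilon_{sh}\,
#'   \frac{\gamma^3 + 2W}{\gamma^3 - W}, \quad
#'   \gamma = \frac{R}{R-d}, \quad
#'   W = \frac{\varepsilon_{in}-\varepsilon_{sh}}
#'            {\varepsilon_{in}+2\varepsilon_{sh}}.}
#' Applied recursively this yields the standard multi-shell cell model.
#'
#' @param inner complex permittivity of the core (F/m), possibly a vector
#'   over frequency.
#' @param shell complex permittivity of the shell (F/m), same length or
#'   length 1.
#' @param outer_radius total radius R in m.
#' @param shell_thickness shell thickness d in m, `0 < d < R`.
#' @return Equivalent complex permittivity, F/m.
#' @export
shelled_sphere_equivalent <- function(inner, shell, outer_radius,
                                      shell_thickness) {
  if (!(shell_thickness > 0) || shell_thickness >= outer_radius)
    stop("'shell_thickness' must satisfy 0 < d < outer_radius")
  g3 <- (outer_radius / (outer_radius - shell_thickness))^3
  W <- (inner - shell) / (inner + 2 * shell)
  shell * (g3 + 2 * W) / (g3 - W)
}

#' Equivalent homogeneous permittivity of a (possibly nucleated) cell
#'
#' Builds the spherical multi-shell equivalent permittivity
#' \eqn{\varepsilon_2^*} used by the Clausius-Mossotti analysis:
#' nucleoplasm coated by the nuclear envelope gives the nucleus; the nucleus
#' is homogenised into the cytoplasm by Maxwell-Garnett mixing at volume
#' fraction \eqn{(R_n/(R_c-d_m))^3}; the resulting interior is coated by the
#' membrane.  With `include_nucleus = FALSE` (or `scale = 0`) the classic
#' single-shell membrane-plus-cytoplasm model is returned, so the influence
#' of the nuclear compartments on the dielectrophoretic response can be
#' switched on and off.
#'
#' @param geom a [cell_geometry()]; must be spherical (the Clausius-Mossotti
#'   expression used downstream is only valid for spherical cells).
#' @param diel a [cell_dielectrics()].
#' @param frequency frequency in Hz (vectorised).
#' @param include_nucleus logical; homogenise the nucleus into the interior?
#' @return Complex permittivity \eqn{\varepsilon_2^*} in F/m per frequency.
#' @export
cell_equivalent_permittivity <- function(geom, diel, frequency,
                                         include_nucleus = TRUE) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(diel, "cell_dielectrics"))
  if (geom$shape != "sphere")
    stop("unsupported shape: the multi-shell model requires a spherical cell")
  check_frequency(frequency)
  e_cyt <- complex_permittivity(diel$cytoplasm, frequency)
  interior <- e_cyt
  if (include_nucleus && geom$scale > 0) {
    if (is.null(diel$nuclear_envelope))
      stop("nucleated geometry but no nuclear compartment materials given")
    if (!(geom$dn > 0) || geom$dn >= geom$Rn)
      stop("nuclear envelope thickness must satisfy 0 < dn < Rn")
    e_np <- complex_permittivity(diel$nucleoplasm, frequency)
    e_ne <- complex_permittivity(diel$nuclear_envelope, frequency)
    e_nuc <- shelled_sphere_equivalent(e_np, e_ne, geom$Rn, geom$dn)
    p <- (geom$Rn / (geom$Rc - geom$dm))^3
    W <- (e_nuc - e_cyt) / (e_nuc + 2 * e_cyt)
    interior <- e_cyt * (1 + 2 * p * W) / (1 - p * W)
  }
  e_m <- complex_permittivity(diel$membrane, frequency)
  shelled_sphere_equivalent(interior, e_m, geom$Rc, geom$dm)
}

#' Clausius-Mossotti factor
#'
#' \deqn{CM = \frac{\varepsilon_2^* - \varepsilon_1^*}
#'                 {\varepsilon_2^* + 2\varepsilon_1^*}}
#' for a spherical particle (\eqn{\varepsilon_2^*}) suspended in a medium
#' (\eqn{\varepsilon_1^*}).  The sign of the real part sets the direction of
#' the time-averaged dielectrophoretic force: positive towards high-field
#' regions, negative towards low-field regions.  For passive materials the
#' real part lies in \eqn{[-0.5, 1]}.
#'
#' @param medium complex permittivity of the suspending medium, F/m
#'   (vectorised).
#' @param particle complex permittivity of the particle, F/m.
#' @return Complex CM factor (dimensionless).
#' @export
cm_factor <- function(medium, particle) {
  if (any(Mod(medium) == 0))
    stop("medium permittivity must be non-zero")
  den <- particle + 2 * medium
  if (any(Mod(den) <= 1e-300 * pmax(Mod(particle), Mod(medium))))
    stop("degenerate denominator in Clausius-Mossotti factor")
  (particle - medium) / den
}

#' First-order induced transmembrane potential (Schwan closed form)
#'
#' Analytic oracle for a spherical cell with a capacitive membrane in a
#' uniform axial field of amplitude `field`:
#' \deqn{\Delta\Phi(\theta) = \frac{1.5\,E\,R_c\cos\theta}{1 + i\omega\tau},
#'   \qquad \tau = R_c\,\frac{\varepsilon_m \varepsilon_0}{d_m}
#'   \left(\frac{1}{\sigma_{cyt}} + \frac{1}{2\sigma_{med}}\right).}
#' Valid when membrane conduction and bulk displacement currents are
#' negligible; used to validate the finite-element solver, not as a
#' production model.
#'
#' @param field uniform field amplitude in V/m.
#' @param geom a spherical [cell_geometry()].
#' @param diel a [cell_dielectrics()]; only membrane permittivity and
#'   cytoplasm conductivity are used.
#' @param medium the external [material()]; its conductivity must be
#'   positive, as must the cytoplasm conductivity.
#' @param frequency frequency in Hz (vectorised).
#' @param polar_angle angle from the field axis in radians (0 = cell apex).
#' @return Complex transmembrane potential in V per frequency.
#' @export
schwan_tmp <- function(field, geom, diel, medium, frequency,
                       polar_angle = 0) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(diel, "cell_dielectrics"),
            inherits(medium, "material"))
  if (geom$shape != "sphere")
    stop("the closed form applies to spherical cells only")
  if (diel$cytoplasm$sigma <= 0 || medium$sigma <= 0)
    stop("cytoplasm and medium conductivities must be positive")
  check_frequency(frequency)
  cm_area <- diel$membrane$eps_r * EPS0 / geom$dm   # F/m^2
  tau <- geom$Rc * cm_area *
    (1 / diel$cytoplasm$sigma + 1 / (2 * medium$sigma))
  omega <- 2 * pi * frequency
  1.5 * field * geom$Rc * cos(polar_angle) / (1 + 1i * omega * tau)
}
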