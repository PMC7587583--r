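# UQ-ready model wrappers: map a named parameter vector + frequency grid
# to a real-valued spectrum, for the equivalent circuit, the
# Clausius-Mossotti factor, and finite-element probes.

stack_from_params <- function(p, base) {
  g <- function(key, fallback) if (key %in% names(p)) p[[key]] else fallback
  cs <- base$cover_slip; buf <- base$buffer
  r_cs <- g("r_cs", cs$r)
  chamber_stack(
    cover_slip = layer_spec(g("d_cs", cs$d), r_cs,
                            material("cs", cs$material$sigma,
                                     g("eps_cs", cs$material$eps_r))),
    buffer = layer_spec(g("d_buf", buf$d), r_cs,
                        material("buf", g("sigma_buf", buf$material$sigma),
                                 g("eps_buf", buf$material$eps_r))),
    V0 = base$V0
  )
}

#' Equivalent-circuit model for uncertainty studies
#'
#' Returns a `function(params, frequencies)` evaluating the chamber
#' impedance magnitude or the field magnitude in the medium.  Recognised
#' parameter names: `d_cs`, `r_cs`, `eps_cs`, `d_buf`, `sigma_buf`,
#' `eps_buf` (SI units); the medium radius is tied to the cover-slip
#' radius.  Unlisted parameters keep the values of `base`.
#'
#' @param quantity `"abs_impedance"` (ohm) or `"field"` (V/m).
#' @param base a [chamber_stack()] providing the nominal values.
#' @return A model function for [uq_study()].
#' @export
circuit_uq_model <- function(quantity = c("abs_impedance", "field"),
                             base = default_chamber()) {
  quantity <- match.arg(quantity)
  force(base)
  function(params, frequencies) {
    st <- stack_from_params(as.list(params), base)
    if (quantity == "abs_impedance")
      Mod(chamber_impedance(st, frequencies))
    else
      Mod(buffer_field(st, frequencies))
  }
}

#' Input distributions of the circuit uncertainty study
#'
#' Six uncertain parameters: geometry uniform within +/- 10% of the
#' printed values (cover-slip thickness and radius, medium thickness),
#' cover-slip permittivity +/- 10% around 4, medium conductivity
#' U(0.5, 1.5) S/m and medium permittivity U(60, 80).
#'
#' @return List of [param_uniform()] objects.
#' @export
circuit_distributions <- function() {
  list(param_pm10("d_cs", 0.15e-3),
       param_pm10("r_cs", 16.5e-3),
       param_pm10("eps_cs", 4),
       param_pm10("d_buf", 1.415e-3),
       param_uniform("sigma_buf", 0.5, 1.5),
       param_uniform("eps_buf", 60, 80))
}

#' Clausius-Mossotti model for uncertainty studies
#'
#' Returns a `function(params, frequencies)` computing the real part of
#' the CM factor of a nucleated spherical cell suspended in a conductive
#' hydrogel.  Parameter names: `sigma_hydro`, `eps_hydro`, `sigma_m`,
#' `eps_m`, `sigma_cyt`, `eps_cyt`, `sigma_ne`, `eps_ne`, `sigma_np`,
#' `eps_np`, `R_c` (m), `d_m` (m), `scale`, `d_n` (m).
#'
#' @param include_nucleus forwards to [cell_equivalent_permittivity()];
#'   both modes are available because it is not obvious a priori whether
#'   the nuclear compartments change the dielectrophoretic response.
#' @return A model function for [uq_study()].
#' @export
cm_uq_model <- function(include_nucleus = TRUE) {
  force(include_nucleus)
  function(params, frequencies) {
    p <- as.list(params)
    geom <- cell_geometry("sphere", Rc = p$R_c, dm = p$d_m,
                          scale = if (include_nucleus) p$scale else 0,
                          dn = p$d_n)
    diel <- cell_dielectrics(
      membrane = material("m", p$sigma_m, p$eps_m),
      cytoplasm = material("cyt", p$sigma_cyt, p$eps_cyt),
      nuclear_envelope = material("ne", p$sigma_ne, p$eps_ne),
      nucleoplasm = material("np", p$sigma_np, p$eps_np)
    )
    hydro <- material("hydro", p$sigma_hydro, p$eps_hydro)
    e1 <- complex_permittivity(hydro, frequencies)
    e2 <- cell_equivalent_permittivity(geom, diel, frequencies,
                                       include_nucleus = include_nucleus)
    Re(cm_factor(e1, e2))
  }
}

#' Input distributions of the Clausius-Mossotti study
#'
#' Hydrogel: conductivity U(0.1, 2.0) S/m, permittivity U(60, 1000).
#' Cell compartments (eukaryotic ranges): membrane U(8e-8, 5.6e-5) S/m,
#' U(1.4, 16.8); cytoplasm U(0.033, 1.1) S/m, U(60, 77); nuclear envelope
#' U(8.3e-5, 7e-3) S/m, U(6.8, 100); nucleoplasm U(0.25, 2.2) S/m,
#' U(32, 300).  Geometry: cell radius U(3.5, 10.5) um, membrane thickness
#' U(3.5, 10.5) nm, nucleus scale U(0.28, 0.84), envelope thickness
#' U(20, 60) nm.
#'
#' @return List of [param_uniform()] objects (14 parameters).
#' @export
cm_distributions <- function() {
  list(param_uniform("sigma_hydro", 0.1, 2.0),
       param_uniform("eps_hydro", 60, 1e3),
       param_uniform("sigma_m", 8e-8, 5.6e-5),
       param_uniform("eps_m", 1.4, 16.8),
       param_uniform("sigma_cyt", 0.033, 1.1),
       param_uniform("eps_cyt", 60, 77),
       param_uniform("sigma_ne", 8.3e-5, 7e-3),
       param_uniform("eps_ne", 6.8, 100),
       param_uniform("sigma_np", 0.25, 2.2),
       param_uniform("eps_np", 32, 300),
       param_uniform("R_c", 3.5e-6, 10.5e-6),
       param_uniform("d_m", 3.5e-9, 10.5e-9),
       param_uniform("scale", 0.28, 0.84),
       param_uniform("d_n", 20e-9, 60e-9))
}

#' Finite-element transmembrane-potential model for uncertainty studies
#'
#' Wraps a prepared [fem_system()] of a cell-bearing scenario as a UQ
#' model returning `|TMP|` at a membrane probe.  Recognised parameters:
#' `sigma_hydro`, `eps_hydro`, `sigma_buf`, `eps_buf`, `sigma_m`, `eps_m`,
#' `sigma_cyt`, `eps_cyt` (any subset; the rest keep `materials`).  The
#' mesh geometry is fixed, so geometric parameters are not part of this
#' model.
#'
#' @param system a [fem_system()] whose mesh carries a membrane.
#' @param materials nominal named material list for the mesh regions.
#' @param membrane_thickness membrane thickness in m.
#' @param V0 applied voltage amplitude in V.
#' @param probe membrane probe passed to [probe_tmp()].
#' @return A model function for [uq_study()].
#' @export
fem_tmp_uq_model <- function(system, materials, membrane_thickness,
                             V0 = 44.81, probe = "top") {
  stopifnot(inherits(system, "fem_system"))
  force(materials); force(membrane_thickness); force(V0); force(probe)
  function(params, frequencies) {
    p <- as.list(params)
    gp <- function(key, fallback)
      if (key %in% names(p)) p[[key]] else fallback
    mats <- materials
    for (tag in intersect(names(mats), c("hydro", "buf", "cyt"))) {
      m <- mats[[tag]]
      mats[[tag]] <- material(tag, gp(paste0("sigma_", tag), m$sigma),
                              gp(paste0("eps_", tag), m$eps_r))
    }
    mem <- material("m", gp("sigma_m", 0), gp("eps_m", 11.3))
    vapply(frequencies, function(f) {
      sol <- solve_eqs(system, mats, f, V0,
                       membrane = list(material = mem,
                                       thickness = membrane_thickness))
      Mod(probe_tmp(sol, probe))
    }, numeric(1))
  }
}
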