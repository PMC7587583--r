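# Named scenario presets reproducing each figure-level experiment, plus
# deterministic fixtures for tests.  Configs store lengths in mm (the
# printed convention); everything is converted to SI metres on use.

#' Reference material set of the numerical model
#'
#' Insulator/lid plastic: sigma 0, eps_r 2.6; glass cover slip: 0, 4;
#' culture medium: 1.5 S/m, 80; cytoplasm: 1.5 S/m, 60; cell membrane:
#' 0 S/m, 11.3.
#'
#' @return Named list of [material()] objects (`ins`, `cs`, `buf`, `cyt`,
#'   `m`).
#' @export
reference_materials <- function() {
  list(ins = material("ins", 0, 2.6),
       cs = material("cs", 0, 4),
       buf = material("buf", 1.5, 80),
       cyt = material("cyt", 1.5, 60),
       m = material("m", 0, 11.3))
}

#' Scenario presets
#'
#' Fully populated configurations for the package's study scenarios:
#'
#' * `circuit_validation`: the layered chamber alone (equivalent circuit
#'   vs FEM validation).
#' * `benchmark_adherent_cell`: oblate cell near the bottom cover slip,
#'   the classic 2D-culture benchmark.
#' * `elliptical_on_hydrogel`: the same oblate cell resting on the
#'   hydrogel block.
#' * `spherical_on_hydrogel_interface`: spherical cell straddling the
#'   hydrogel--medium interface.
#' * `spherical_centred_in_hydrogel`: spherical cell at the centre of the
#'   scaffold.
#' * `cm_factor_study`: distribution set for the Clausius-Mossotti
#'   uncertainty study (no mesh).
#'
#' @param name one of the preset names above.
#' @return An object of class `scenario_config`.
#' @export
preset <- function(name = c("circuit_validation", "benchmark_adherent_cell",
                            "elliptical_on_hydrogel",
                            "spherical_on_hydrogel_interface",
                            "spherical_centred_in_hydrogel",
                            "cm_factor_study")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% eval(formals(preset)$name))
    stop("unknown preset: ", paste(name, collapse = ", "))
  mats <- reference_materials()
  cfg <- list(
    name = name,
    d_cs_mm = 0.15, r_cs_mm = 16.5, d_buf_mm = 1.415, v0_v = 44.81,
    materials = list(
      cs = list(sigma = 0, eps_r = 4),
      buf = list(sigma = 1.5, eps_r = 80),
      cyt = list(sigma = 1.5, eps_r = 60),
      m = list(sigma = 0, eps_r = 11.3),
      hydro = list(sigma = 1.5, eps_r = 80)
    ),
    hydrogel = NULL, cell = NULL, distributions = NULL,
    freq = list(n = 61, from_hz = 10, to_hz = 1e8, extra_hz = 6e4)
  )
  sphere <- list(shape = "sphere", a_r_um = 7, a_z_um = 7, dm_nm = 7)
  oblate <- list(shape = "oblate_ellipsoid", a_r_um = 10, a_z_um = 2.5,
                 dm_nm = 7)
  gel <- list(radius_mm = 1, height_mm = 1)
  if (name == "benchmark_adherent_cell") {
    cfg$cell <- c(oblate, placement = "adherent_bottom")
  } else if (name == "elliptical_on_hydrogel") {
    cfg$hydrogel <- gel
    cfg$cell <- c(oblate, placement = "elliptical_on_hydrogel")
  } else if (name == "spherical_on_hydrogel_interface") {
    cfg$hydrogel <- gel
    cfg$cell <- c(sphere, placement = "spherical_on_hydrogel_interface")
  } else if (name == "spherical_centred_in_hydrogel") {
    cfg$hydrogel <- gel
    cfg$cell <- c(sphere, placement = "spherical_centred_in_hydrogel")
  } else if (name == "cm_factor_study") {
    cfg$distributions <- cm_distributions()
  }
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s%s%s\n", x$name,
              if (!is.null(x$hydrogel)) " + hydrogel" else "",
              if (!is.null(x$cell)) paste0(" + cell (", x$cell$placement, ")")
              else ""))
  invisible(x)
}

#' Chamber stack of a scenario
#'
#' @param scenario a [preset()] configuration.
#' @return A [chamber_stack()] in SI units.
#' @export
scenario_stack <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  m <- scenario$materials
  chamber_stack(
    cover_slip = layer_spec(scenario$d_cs_mm * 1e-3, scenario$r_cs_mm * 1e-3,
                            material("cs", m$cs$sigma, m$cs$eps_r)),
    buffer = layer_spec(scenario$d_buf_mm * 1e-3, scenario$r_cs_mm * 1e-3,
                        material("buf", m$buf$sigma, m$buf$eps_r)),
    V0 = scenario$v0_v
  )
}

#' Region material map of a scenario mesh
#'
#' @param scenario a [preset()] configuration.
#' @param sigma_hydro,eps_hydro optional hydrogel property overrides.
#' @return Named list of [material()] objects keyed by mesh region tag.
#' @export
scenario_materials <- function(scenario, sigma_hydro = NULL,
                               eps_hydro = NULL) {
  m <- scenario$materials
  out <- list(
    cs_bot = material("cs", m$cs$sigma, m$cs$eps_r),
    cs_top = material("cs", m$cs$sigma, m$cs$eps_r),
    buf = material("buf", m$buf$sigma, m$buf$eps_r)
  )
  if (!is.null(scenario$hydrogel))
    out$hydro <- material("hydro", sigma_hydro %||% m$hydro$sigma,
                          eps_hydro %||% m$hydro$eps_r)
  if (!is.null(scenario$cell))
    out$cyt <- material("cyt", m$cyt$sigma, m$cyt$eps_r)
  out
}

#' Build the mesh of a scenario
#'
#' Dispatches to [mesh_stack()] or [mesh_chamber_cell()] according to the
#' scenario contents.  Refinement level `+1` halves target element sizes
#' (and at least doubles the element count around the cell); the base
#' level resolves the cell radius with at least 8 elements.
#'
#' @param scenario a [preset()] configuration.
#' @param refinement non-negative integer.
#' @return An `eqs_mesh`.
#' @export
build_geometry <- function(scenario, refinement = 0) {
  stopifnot(inherits(scenario, "scenario_config"))
  st <- scenario_stack(scenario)
  gel <- if (!is.null(scenario$hydrogel))
    list(radius = scenario$hydrogel$radius_mm * 1e-3,
         height = scenario$hydrogel$height_mm * 1e-3)
  if (!is.null(scenario$hydrogel) &&
      gel$height > st$buffer$d)
    stop("hydrogel taller than the medium layer")
  if (is.null(scenario$cell))
    return(mesh_stack(st, hydrogel = gel, refinement = refinement))
  cl <- scenario$cell
  mesh_chamber_cell(st, hydrogel = gel, placement = cl$placement,
                    a_r = cl$a_r_um * 1e-6, a_z = cl$a_z_um * 1e-6,
                    refinement = refinement)
}

#' Write / read a scenario configuration
#'
#' YAML serialisation with unit-suffixed keys (lengths in mm); the
#' round-trip is lossless.
#'
#' @param scenario a [preset()]-style configuration.
#' @param path file path.
#' @return `read_scenario()` returns the `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_config"))
  x <- unclass(scenario)
  if (!is.null(x$distributions))
    x$distributions <- lapply(x$distributions, function(d)
      list(name = d$name, kind = d$kind, low = d$low, high = d$high))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$distributions))
    x$distributions <- lapply(x$distributions, function(d)
      param_uniform(d$name, d$low, d$high))
  structure(x, class = "scenario_config")
}

#' Deterministic test fixtures
#'
#' * `toy_box_cell`: uniform-field cylindrical box (100 um) with one
#'   spherical cell (radius 5 um) for the analytic transmembrane-potential
#'   oracle; bulk permittivities are set to 1 so the first-order membrane
#'   charging model holds over the whole frequency band.
#' * `analytic_models`: small closed-form UQ test models (linear and
#'   quadratic in their parameters) with their exact means, variances and
#'   first-order Sobol indices.
#' * `tiny_mesh`: a coarse chamber mesh that solves in well under a
#'   second.
#'
#' @param kind fixture name.
#' @param seed integer seed (kept for interface symmetry; the fixtures are
#'   deterministic).
#' @return A list of fixture components (see details above).
#' @export
make_fixture <- function(kind = c("toy_box_cell", "analytic_models",
                                  "tiny_mesh"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "toy_box_cell") {
    Rc <- 5e-6; H <- 100e-6
    mesh <- mesh_box_cell(box_height = H, box_radius = H, a_r = Rc, a_z = Rc)
    med <- material("med", 1.5, 1)
    list(mesh = mesh,
         materials = list(med = med, cyt = material("cyt", 1.5, 1)),
         membrane = list(material = material("m", 0, 11.3),
                         thickness = 7e-9),
         medium = med,
         geom = cell_geometry("sphere", Rc = Rc, dm = 7e-9),
         diel = cell_dielectrics(material("m", 0, 11.3),
                                 material("cyt", 1.5, 1)),
         box_height = H, V0_per_field = H)
  } else if (kind == "analytic_models") {
    # f = 2 X1 + 3 X2 on U(0,1)^2: V_i = coef^2 / 12
    lin <- list(
      model = function(p, freqs) rep(2 * p[["x1"]] + 3 * p[["x2"]],
                                     length(freqs)),
      dists = list(param_uniform("x1", 0, 1), param_uniform("x2", 0, 1)),
      mean = 2.5, var = 13 / 12,
      sobol = c(x1 = 4 / 13, x2 = 9 / 13)
    )
    # f = X1^2 on U(0,1): mean 1/3, var 4/45
    quad <- list(
      model = function(p, freqs) rep(p[["x1"]]^2, length(freqs)),
      dists = list(param_uniform("x1", 0, 1)),
      mean = 1 / 3, var = 4 / 45, sobol = c(x1 = 1)
    )
    list(linear = lin, quadratic = quad)
  } else {
    st <- default_chamber()
    list(mesh = mesh_stack(st), stack = st,
         materials = list(cs_bot = st$cover_slip$material,
                          cs_top = st$cover_slip$material,
                          buf = st$buffer$material))
  }
}
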