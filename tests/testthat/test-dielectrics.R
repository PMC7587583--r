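test_that("complex permittivity follows the lossy-dielectric convention", {
  # vacuum identity
  vac <- material("vac", 0, 1)
  expect_identical(complex_permittivity(vac, 123), complex(real = EPS0))

  # culture medium at 60 kHz: eps_r*eps0 - i sigma/omega
  buf <- material("buf", 1.5, 80)
  e <- complex_permittivity(buf, 60e3)
  expect_equal(Re(e), 80 * EPS0)
  expect_equal(Im(e), -1.5 / (2 * pi * 60e3))
  expect_equal(Re(e), 7.08e-10, tolerance = 1e-3)
  expect_equal(Im(e), -3.98e-6, tolerance = 1e-3)

  # imaginary part is <= 0 and vanishes monotonically with frequency
  fs <- freq_grid(31)
  im <- Im(complex_permittivity(buf, fs))
  expect_true(all(im <= 0))
  expect_true(all(diff(im) > 0))

  expect_error(complex_permittivity(buf, 0), "positive")
  expect_error(material("x", -1, 80), "non-negative")
})

test_that("shelled-sphere reduction has the correct limits and matches the
          boundary-value oracle", {
  f <- 1e3
  med <- complex_permittivity(material("med", 1, 80), f)
  e_in <- 60 * EPS0 - 1i * 1.5 / (2 * pi * f)
  e_sh <- complex_permittivity(material("m", 0, 11.3), f)

  # shell material identical to the core: no-op
  expect_equal(shelled_sphere_equivalent(e_in, e_in, 5e-6, 1e-7), e_in)

  # vanishing shell thickness recovers the core (lossless pair, where the
  # limit is well conditioned; the lossy case is covered by the oracle)
  a <- complex(real = 60 * EPS0); b <- complex(real = 11.3 * EPS0)
  thin <- shelled_sphere_equivalent(a, b, 5e-6, 1e-13)
  expect_lt(Mod(thin - a) / Mod(a), 1e-6)
  # and the limit tightens as the shell gets thinner
  thin2 <- shelled_sphere_equivalent(e_in, e_sh, 5e-6, 1e-12)
  thin3 <- shelled_sphere_equivalent(e_in, e_sh, 5e-6, 1e-13)
  expect_lt(Mod(thin3 - e_in), 0.2 * Mod(thin2 - e_in))

  # independent oracle: direct Laplace boundary-value solution
  impl <- shelled_sphere_equivalent(e_in, e_sh, 5e-6, 7e-9)
  K <- oracle_cm_multishell(c(5e-6 - 7e-9, 5e-6), c(e_in, e_sh), med)
  expect_equal(impl, oracle_eps_from_cm(K, med), tolerance = 1e-10)

  expect_error(shelled_sphere_equivalent(e_in, e_sh, 5e-6, 5e-6),
               "shell_thickness")
})

test_that("cell equivalent permittivity reduces correctly and matches the
          multishell oracle on random parameter draws", {
  f <- 1e6
  mem <- material("m", 0, 11.3)
  cyt <- material("cyt", 1.5, 60)
  # nucleus removed -> single-shell value
  g0 <- cell_geometry("sphere", Rc = 5e-6, dm = 7e-9, scale = 0)
  d0 <- cell_dielectrics(mem, cyt)
  e_single <- shelled_sphere_equivalent(complex_permittivity(cyt, f),
                                        complex_permittivity(mem, f),
                                        5e-6, 7e-9)
  expect_equal(cell_equivalent_permittivity(g0, d0, f), e_single)

  # near-vanishing membrane -> bare cytoplasm
  g1 <- cell_geometry("sphere", Rc = 5e-6, dm = 1e-14, scale = 0)
  expect_equal(cell_equivalent_permittivity(g1, d0, f),
               complex_permittivity(cyt, f), tolerance = 1e-6)

  # ellipsoid is rejected (the CM model is spherical)
  ge <- cell_geometry("oblate_ellipsoid", Rc = 5e-6, dm = 7e-9)
  expect_error(cell_equivalent_permittivity(ge, d0, f), "spherical")

  # 100 random draws from the eukaryotic parameter tables vs the
  # boundary-value oracle
  X <- draw_cell_params(100, 42)
  errs <- vapply(seq_len(nrow(X)), function(i) {
    p <- as.list(X[i, ])
    geom <- cell_geometry("sphere", Rc = p$R_c, dm = p$d_m,
                          scale = p$scale, dn = p$d_n)
    diel <- cell_dielectrics(
      material("m", p$sigma_m, p$eps_m),
      material("cyt", p$sigma_cyt, p$eps_cyt),
      material("ne", p$sigma_ne, p$eps_ne),
      material("np", p$sigma_np, p$eps_np))
    e2 <- cell_equivalent_permittivity(geom, diel, f)
    emed <- complex_permittivity(material("h", p$sigma_hydro, p$eps_hydro), f)
    Rn <- p$scale * p$R_c
    Ko <- oracle_cm_multishell(
      c(Rn - p$d_n, Rn, p$R_c - p$d_m, p$R_c),
      c(complex_permittivity(material("np", p$sigma_np, p$eps_np), f),
        complex_permittivity(material("ne", p$sigma_ne, p$eps_ne), f),
        complex_permittivity(material("cyt", p$sigma_cyt, p$eps_cyt), f),
        complex_permittivity(material("m", p$sigma_m, p$eps_m), f)),
      emed)
    Mod(cm_factor(emed, e2) - Ko) / Mod(Ko)
  }, numeric(1))
  expect_lt(max(errs), 1e-10)
})

test_that("Clausius-Mossotti factor limits and bounds hold", {
  f <- 1e3
  med <- complex_permittivity(material("med", 1, 80), f)

  # index-matched particle
  expect_equal(cm_factor(med, med), 0 + 0i)

  # conducting sphere at low frequency -> +1
  hi <- complex_permittivity(material("metal", 1e9, 80), f)
  expect_equal(Re(cm_factor(med, hi)), 1, tolerance = 1e-6)

  # insulating sphere in a conductive medium -> -1/2
  lo <- complex_permittivity(material("ins", 0, 2), f)
  expect_equal(Re(cm_factor(med, lo)), -0.5, tolerance = 1e-3)

  # real part bounded in [-0.5, 1] over the full cell/hydrogel parameter
  # box, swept over the working band
  X <- draw_cell_params(50, 7)
  fs <- freq_grid(15)
  model <- cm_uq_model(include_nucleus = TRUE)
  for (i in seq_len(nrow(X))) {
    re <- model(X[i, ], fs)
    expect_true(all(re >= -0.5 - 1e-9 & re <= 1 + 1e-9))
  }
})

test_that("first-order transmembrane potential closed form behaves", {
  geom <- cell_geometry("sphere", Rc = 5e-6, dm = 7e-9)
  diel <- cell_dielectrics(material("m", 0, 11.3), material("cyt", 1.5, 60))
  med <- material("med", 1.5, 80)

  # quasi-DC apex value 1.5*E*Rc
  expect_equal(Mod(schwan_tmp(100, geom, diel, med, 1e-3 / (2 * pi))),
               0.75e-3, tolerance = 1e-6)

  # equatorial node at any frequency
  expect_equal(Mod(schwan_tmp(100, geom, diel, med, 1e6, pi / 2)), 0)

  # first-order low-pass: at omega = 1/tau the magnitude is DC/sqrt(2)
  tau <- geom$Rc * (11.3 * EPS0 / geom$dm) * (1 / 1.5 + 1 / 3)
  f_c <- 1 / (2 * pi * tau)
  expect_equal(Mod(schwan_tmp(100, geom, diel, med, f_c)),
               0.75e-3 / sqrt(2), tolerance = 1e-9)

  # magnitude monotonically non-increasing in frequency
  m <- Mod(schwan_tmp(100, geom, diel, med, freq_grid(25)))
  expect_true(all(diff(m) <= 0))

  expect_error(schwan_tmp(100, geom,
                          cell_dielectrics(material("m", 0, 11.3),
                                           material("cyt", 0, 60)),
                          med, 1e3), "positive")
})
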