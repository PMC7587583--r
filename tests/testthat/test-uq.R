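test_that("collocation plan size follows the 2*terms + 2 rule", {
  expect_identical(pc_node_count(6, 4), 422L)
  expect_identical(pc_node_count(1, 1), 6L)
  expect_identical(pc_node_count(3, 2), 22L)
  expect_error(pc_node_count(0, 4))
})

test_that("sampling is reproducible and respects the declared bounds", {
  d <- list(param_uniform("a", 0.5, 1.5), param_uniform("b", -2, 7))
  x1 <- sample_mc(d, 500, seed = 99)
  x2 <- sample_mc(d, 500, seed = 99)
  expect_identical(x1, x2)
  expect_false(identical(x1, sample_mc(d, 500, seed = 100)))
  expect_true(all(x1[, "a"] >= 0.5 & x1[, "a"] <= 1.5))
  expect_true(all(x1[, "b"] >= -2 & x1[, "b"] <= 7))
  expect_equal(mean(x1[, "a"]), 1, tolerance = 3 * sqrt(1 / 12) / sqrt(500))
  expect_error(param_uniform("x", 2, 2), "smaller")
})

test_that("polynomial-chaos surrogate reproduces polynomial models
          exactly and cross-validates on the circuit model", {
  fx <- make_fixture("analytic_models")
  # linear model, order 1: exact at held-out points
  lin <- fx$linear
  X <- sample_mc(lin$dists, pc_node_count(2, 1), seed = 4)
  surr <- build_pc_surrogate(X, eval_grid <- t(vapply(
    seq_len(nrow(X)), function(i) lin$model(X[i, ], 1:2), numeric(2))),
    order = 1, distributions = lin$dists)
  Xnew <- sample_mc(lin$dists, 50, seed = 5)
  truth <- t(vapply(seq_len(50), function(i) lin$model(Xnew[i, ], 1:2),
                    numeric(2)))
  expect_equal(max(abs(predict(surr, Xnew) - truth)), 0, tolerance = 1e-10)

  # quadratic model, order 2: exact coefficient recovery
  qd <- fx$quadratic
  Xq <- sample_mc(qd$dists, pc_node_count(1, 2), seed = 6)
  sq <- build_pc_surrogate(Xq, matrix(Xq[, 1]^2, ncol = 1), 2, qd$dists)
  # mean coefficient is the analytic mean; total variance matches
  expect_equal(sq$coef[1, 1], qd$mean, tolerance = 1e-12)
  expect_equal(sum(sq$coef[-1, 1]^2), qd$var, tolerance = 1e-12)

  # under-determined regression is refused
  expect_error(build_pc_surrogate(Xq[1:3, , drop = FALSE],
                                  matrix(Xq[1:3, 1]^2, ncol = 1),
                                  4, qd$dists), "at least")

  # circuit impedance, order 4: relative error < 1e-3 at random points
  model <- circuit_uq_model("abs_impedance")
  dists <- circuit_distributions()
  fs <- freq_grid(5)
  Xc <- sample_mc(dists, pc_node_count(6, 4), seed = 8)
  Yc <- t(vapply(seq_len(nrow(Xc)), function(i) model(Xc[i, ], fs),
                 numeric(5)))
  sc_ <- build_pc_surrogate(Xc, Yc, 4, dists)
  Xv <- sample_mc(dists, 100, seed = 9)
  Yv <- t(vapply(seq_len(100), function(i) model(Xv[i, ], fs), numeric(5)))
  expect_lt(max(abs(predict(sc_, Xv) - Yv) / Yv), 1e-3)
})

test_that("first-order Sobol indices recover closed-form variance
          decompositions", {
  fx <- make_fixture("analytic_models")
  # single uncertain parameter: all variance from one source
  r1 <- run_study(uq_study(fx$quadratic$model, fx$quadratic$dists, "pc",
                           frequencies = 1, order = 2, seed = 2))
  expect_equal(unname(r1$sobol[1, 1]), 1, tolerance = 1e-9)

  # additive model: S_i = a_i^2 V_i / sum a_j^2 V_j, exactly from PC and
  # within estimator noise from Saltelli MC
  lin <- fx$linear
  rpc <- run_study(uq_study(lin$model, lin$dists, "pc", frequencies = 1,
                            order = 1, seed = 2))
  expect_equal(unname(rpc$sobol[1, ]), unname(lin$sobol), tolerance = 1e-9)
  expect_equal(unname(rpc$mean), lin$mean, tolerance = 1e-9)
  rmc <- run_study(uq_study(lin$model, lin$dists, "mc", frequencies = 1,
                            n_samples = 12000, seed = 2))
  expect_equal(unname(rmc$sobol[1, ]), unname(lin$sobol), tolerance = 0.05)

  # circuit impedance: cover-slip geometry and permittivity dominate the
  # medium parameters
  r <- run_study(uq_study(circuit_uq_model("abs_impedance"),
                          circuit_distributions(), "pc",
                          frequencies = freq_grid(7), order = 4, seed = 3))
  s <- sobol_first_order(r, average = TRUE)
  for (big in c("d_cs", "r_cs", "eps_cs"))
    for (small in c("d_buf", "sigma_buf", "eps_buf"))
      expect_gt(s[[big]], s[[small]])
  # indices do not change with frequency under these assumptions
  # (constant within the collocation-regression estimator noise)
  expect_lt(max(apply(r$sobol, 2, function(x) diff(range(x)))), 0.05)
  # sum of first-order indices stays below one (plus tolerance)
  expect_true(all(rowSums(r$sobol) <= 1.05))
  expect_true(all(rowSums(rmc$sobol) <= 1.05))
})

test_that("prediction intervals are pointwise percentiles", {
  const <- matrix(5, nrow = 50, ncol = 3)
  pi_ <- prediction_interval(const)
  expect_equal(pi_$lower, rep(5, 3)); expect_equal(pi_$upper, rep(5, 3))

  set.seed(1)
  u <- matrix(runif(20000), ncol = 2)
  pu <- prediction_interval(u)
  expect_equal(pu$lower, c(0.05, 0.05), tolerance = 0.05)
  expect_equal(pu$upper, c(0.95, 0.95), tolerance = 0.05)

  expect_error(prediction_interval(u[1:10, ]), "at least 20")
})

test_that("full studies: MC and PC agree on the circuit spectrum and are
          reproducible bit for bit", {
  model <- circuit_uq_model("abs_impedance")
  dists <- circuit_distributions()
  fs <- freq_grid(9)
  rpc <- run_study(uq_study(model, dists, "pc", frequencies = fs,
                            order = 4, seed = 12))
  rmc <- run_study(uq_study(model, dists, "mc", frequencies = fs,
                            n_samples = 16000, seed = 12))
  expect_identical(rpc$n_evals, 422L)
  expect_identical(rmc$n_evals, 16000L)
  expect_true(all(abs(rmc$mean - rpc$mean) / rpc$mean < 0.01))
  # interval brackets the mean; mean roughly centred
  for (r in list(rpc, rmc)) {
    expect_true(all(r$lower <= r$mean & r$mean <= r$upper))
    expect_true(all((r$mean - r$lower) / (r$upper - r$lower) > 0.25))
    expect_true(all((r$mean - r$lower) / (r$upper - r$lower) < 0.75))
  }
  # bit-for-bit reproducibility under a fixed seed
  again <- run_study(uq_study(model, dists, "mc", frequencies = fs,
                              n_samples = 16000, seed = 12))
  expect_identical(rmc$mean, again$mean)
  expect_identical(rmc$sobol, again$sobol)

  # a failing model aborts the study with a located error
  bad <- function(p, f) if (p[["sigma_buf"]] > 0.6) rep(1, length(f)) else
    stop("numerical breakdown")
  expect_error(run_study(uq_study(bad, dists, "mc", frequencies = 1,
                                  n_samples = 80, seed = 1)),
               "model evaluation failed")
})

test_that("the dielectrophoretic response of cells in conductive
          hydrogels is push-away at low and high frequency", {
  fs <- freq_grid(17)
  r <- run_study(uq_study(cm_uq_model(TRUE), cm_distributions(), "mc",
                          frequencies = fs, n_samples = 2400, seed = 11))
  expect_true(all(r$mean[fs < 1e6] < 0))
  expect_true(all(r$mean[fs >= 1e8] < 0))
  # the 95th percentile becomes positive only in the megahertz window:
  # negative through 100 kHz, positive somewhere in 1-100 MHz, negative
  # again at the top of the band (the computed zero crossing sits near
  # 0.5 MHz, slightly below the nominal 1 MHz edge)
  expect_true(all(r$upper[fs <= 1e5] < 0))
  expect_true(any(r$upper[fs >= 1e6 & fs <= 1e8] > 0))
  expect_lt(r$upper[length(fs)], 0)
  # switching the nucleus off keeps the low-frequency response
  r0 <- run_study(uq_study(cm_uq_model(FALSE), cm_distributions(), "mc",
                           frequencies = c(1e4), n_samples = 1600,
                           seed = 11))
  expect_lt(r0$mean, 0)
})
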