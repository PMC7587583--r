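# Uncertainty propagation over scalar-spectrum models.
#
# A "model" is a function(params, frequencies) returning one real value per
# frequency, with params a named numeric vector.  Two propagation routes:
#   * Monte Carlo on a Saltelli design (A, B, AB_i blocks), giving mean,
#     percentile prediction interval and first-order Sobol indices;
#   * point-collocation polynomial chaos: regression of model evaluations
#     at sampled nodes onto a total-degree orthonormal Legendre basis
#     matched to the uniform input distributions; mean, variance and Sobol
#     indices come from the coefficients, the prediction interval from
#     cheap surrogate sampling.

#' A uniformly distributed uncertain parameter
#'
#' @param name parameter label, must match a model parameter name.
#' @param low,high bounds in the parameter's own units, `low < high`.
#' @return An object of class `param_distribution`.
#' @export
param_uniform <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(low < high)) stop("'low' must be smaller than 'high'")
  structure(list(name = name, kind = "uniform", low = low, high = high),
            class = "param_distribution")
}

#' Uniform distribution with +/- 10% bounds around a mean
#'
#' The convention used for geometric parameters: uniform on
#' `[0.9 m, 1.1 m]`.
#'
#' @param name parameter label.
#' @param mean central value.
#' @return A [param_uniform()].
#' @export
param_pm10 <- function(name, mean) {
  stopifnot(mean > 0)
  param_uniform(name, 0.9 * mean, 1.1 * mean)
}

dist_names <- function(distributions)
  vapply(distributions, `[[`, character(1), "name")

#' Size of the point-collocation polynomial-chaos sampling plan
#'
#' Twice the number of total-degree-`order` polynomial basis terms in
#' `n_params` variables, plus two:
#' `2 * choose(n_params + order, order) + 2`.  For six parameters at the
#' default order 4 this is 422 model evaluations.
#'
#' @param n_params number of uncertain parameters, >= 1.
#' @param order polynomial order, >= 1 (default 4).
#' @return Integer number of model evaluations.
#' @export
pc_node_count <- function(n_params, order = 4) {
  stopifnot(n_params >= 1, order >= 1)
  as.integer(2 * choose(n_params + order, order) + 2)
}

#' Draw independent samples from the parameter distributions
#'
#' @param distributions list of [param_uniform()] objects.
#' @param n number of draws, >= 1.
#' @param seed integer seed; identical seeds give identical tables.
#' @return Numeric matrix `n x d` with parameter names as columns.
#' @export
sample_mc <- function(distributions, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  d <- length(distributions)
  u <- matrix(stats::runif(n * d), nrow = n)
  lo <- vapply(distributions, `[[`, numeric(1), "low")
  hi <- vapply(distributions, `[[`, numeric(1), "high")
  x <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(x) <- dist_names(distributions)
  x
}

# evaluate model at each sample row -> matrix n x n_freq
eval_model <- function(model, samples, frequencies) {
  out <- matrix(NA_real_, nrow(samples), length(frequencies))
  for (i in seq_len(nrow(samples))) {
    y <- tryCatch(model(samples[i, ], frequencies),
                  error = function(e)
                    stop("model evaluation failed at sample ", i, ": ",
                         conditionMessage(e)))
    if (length(y) != length(frequencies) || anyNA(y))
      stop("model returned an invalid spectrum at sample ", i)
    out[i, ] <- y
  }
  out
}

# ---- polynomial chaos ---------------------------------------------------

total_degree_indices <- function(d, p) {
  if (d == 1) return(matrix(0:p, ncol = 1))
  out <- NULL
  for (k in 0:p)
    out <- rbind(out, cbind(k, total_degree_indices(d - 1, p - k)))
  unname(out)
}

# orthonormal Legendre values on [-1, 1] (uniform measure), cols 0..kmax
legendre_ortho <- function(u, kmax) {
  P <- matrix(0, length(u), kmax + 1)
  P[, 1] <- 1
  if (kmax >= 1) P[, 2] <- u
  if (kmax >= 2)
    for (k in 2:kmax)
      P[, k + 1] <- ((2 * k - 1) * u * P[, k] - (k - 1) * P[, k - 1]) / k
  sweep(P, 2, sqrt(2 * (0:kmax) + 1), "*")
}

pc_design_matrix <- function(samples, distributions, indices) {
  d <- ncol(samples)
  kmax <- max(indices)
  lo <- vapply(distributions, `[[`, numeric(1), "low")
  hi <- vapply(distributions, `[[`, numeric(1), "high")
  leg <- lapply(seq_len(d), function(j) {
    u <- 2 * (samples[, j] - lo[j]) / (hi[j] - lo[j]) - 1
    legendre_ortho(u, kmax)
  })
  Phi <- matrix(1, nrow(samples), nrow(indices))
  for (t in seq_len(nrow(indices)))
    for (j in seq_len(d))
      if (indices[t, j] > 0)
        Phi[, t] <- Phi[, t] * leg[[j]][, indices[t, j] + 1]
  Phi
}

#' Fit a polynomial-chaos surrogate by point collocation
#'
#' Least-squares regression of model evaluations onto the orthonormal
#' Legendre total-degree basis matched to the uniform input distributions.
#'
#' @param samples parameter sample matrix (`n x d`, named columns), e.g.
#'   from [sample_mc()]; `n` must be at least [pc_node_count()] of the
#'   basis.
#' @param model_evals matrix `n x n_freq` of model outputs at the samples.
#' @param order total polynomial degree of the expansion.
#' @param distributions the input distributions the samples were drawn
#'   from.
#' @return An object of class `pc_surrogate` with coefficients, basis
#'   indices, and variance decomposition.
#' @export
build_pc_surrogate <- function(samples, model_evals, order, distributions) {
  model_evals <- as.matrix(model_evals)
  d <- length(distributions)
  stopifnot(ncol(samples) == d, nrow(samples) == nrow(model_evals))
  indices <- total_degree_indices(d, order)
  if (nrow(samples) < nrow(indices))
    stop("need at least ", nrow(indices), " evaluations for order ", order)
  Phi <- pc_design_matrix(samples, distributions, indices)
  fit <- qr(Phi)
  if (fit$rank < ncol(Phi))
    stop("rank-deficient collocation regression; add samples or lower order")
  coef <- qr.coef(fit, model_evals)
  structure(list(coef = coef, indices = indices,
                 distributions = distributions, order = order),
            class = "pc_surrogate")
}

#' Evaluate a polynomial-chaos surrogate
#'
#' @param object a [build_pc_surrogate()] result.
#' @param newdata parameter matrix (`m x d`).
#' @param ... unused.
#' @return Matrix `m x n_freq` of surrogate predictions.
#' @export
predict.pc_surrogate <- function(object, newdata, ...) {
  Phi <- pc_design_matrix(as.matrix(newdata), object$distributions,
                          object$indices)
  Phi %*% object$coef
}

pc_moments <- function(surr) {
  co <- surr$coef
  mean <- co[1, ]
  var <- colSums(co[-1, , drop = FALSE]^2)
  d <- ncol(surr$indices)
  sob <- matrix(NA_real_, length(mean), d)
  for (j in seq_len(d)) {
    only_j <- surr$indices[, j] > 0 &
      rowSums(surr$indices[, -j, drop = FALSE]) == 0
    sob[, j] <- colSums(co[only_j, , drop = FALSE]^2) / var
  }
  list(mean = mean, var = var, sobol = sob)
}

#' Pointwise percentile prediction interval
#'
#' Linear-interpolation percentiles (default 5th and 95th) of model
#' outputs per frequency.
#'
#' @param evaluations matrix `n x n_freq` of model outputs.
#' @param level interval coverage in percent (default 90).
#' @return `list(lower, upper)` spectra.
#' @export
prediction_interval <- function(evaluations, level = 90) {
  evaluations <- as.matrix(evaluations)
  if (nrow(evaluations) < 20)
    stop("need at least 20 evaluations for a percentile interval")
  a <- (100 - level) / 200
  qs <- apply(evaluations, 2, stats::quantile, probs = c(a, 1 - a),
              names = FALSE, type = 7)
  list(lower = qs[1, ], upper = qs[2, ])
}

#' Define an uncertainty-quantification study
#'
#' @param model `function(params, frequencies)` returning a real spectrum.
#' @param distributions list of [param_uniform()] objects covering every
#'   model parameter.
#' @param method `"mc"` (Saltelli Monte Carlo) or `"pc"` (point-collocation
#'   polynomial chaos).
#' @param frequencies frequency grid in Hz.
#' @param n_samples total MC evaluation budget (default 40000; the Saltelli
#'   design uses `n_samples %/% (d + 2)` base draws).
#' @param order PC polynomial order (default 4).
#' @param seed integer seed for all sampling.
#' @return An object of class `uq_study`.
#' @export
uq_study <- function(model, distributions, method = c("mc", "pc"),
                     frequencies = freq_grid(), n_samples = 40000,
                     order = 4, seed = 1) {
  method <- match.arg(method)
  stopifnot(is.function(model), length(distributions) >= 1)
  if (method == "mc" && n_samples < 2) stop("n_samples must be >= 2")
  if (method == "pc" && order < 1) stop("order must be >= 1")
  structure(list(model = model, distributions = distributions,
                 method = method, frequencies = frequencies,
                 n_samples = n_samples, order = order, seed = seed),
            class = "uq_study")
}

#' Run an uncertainty-quantification study
#'
#' Samples the inputs, evaluates the model, and summarises the output
#' spectrum: mean, 90% prediction interval, and first-order Sobol index
#' per parameter per frequency.  MC uses the Saltelli design (the Sobol
#' numerator estimator of Saltelli 2010); PC derives moments and indices
#' from the surrogate coefficients and the interval from surrogate
#' resampling.  All randomness is governed by the study seed.
#'
#' @param study a [uq_study()].
#' @return An object of class `uq_result` with fields `frequencies`,
#'   `mean`, `lower`, `upper`, `sobol` (matrix `n_freq x d`), `n_evals`,
#'   `method`, `parameters`.
#' @export
run_study <- function(study) {
  stopifnot(inherits(study, "uq_study"))
  dists <- study$distributions
  d <- length(dists)
  freqs <- study$frequencies
  nm <- dist_names(dists)

  if (study$method == "mc") {
    n_base <- max(2L, as.integer(study$n_samples) %/% (d + 2L))
    AB <- sample_mc(dists, 2 * n_base, study$seed)
    A <- AB[seq_len(n_base), , drop = FALSE]
    B <- AB[n_base + seq_len(n_base), , drop = FALSE]
    fA <- eval_model(study$model, A, freqs)
    fB <- eval_model(study$model, B, freqs)
    fall <- rbind(fA, fB)
    V <- apply(fall, 2, stats::var)
    sob <- matrix(NA_real_, length(freqs), d)
    n_evals <- 2L * n_base
    for (j in seq_len(d)) {
      ABj <- A; ABj[, j] <- B[, j]
      fABj <- eval_model(study$model, ABj, freqs)
      n_evals <- n_evals + n_base
      sob[, j] <- colMeans(fB * (fABj - fA)) / V
    }
    pi_ <- prediction_interval(fall, 90)
    res <- list(frequencies = freqs, mean = colMeans(fall),
                lower = pi_$lower, upper = pi_$upper, sobol = sob,
                n_evals = n_evals, method = "mc", parameters = nm,
                seed = study$seed)
  } else {
    n_nodes <- pc_node_count(d, study$order)
    X <- sample_mc(dists, n_nodes, study$seed)
    fX <- eval_model(study$model, X, freqs)
    surr <- build_pc_surrogate(X, fX, study$order, dists)
    mo <- pc_moments(surr)
    Xbig <- sample_mc(dists, 4000, study$seed + 1L)
    pred <- predict(surr, Xbig)
    pi_ <- prediction_interval(pred, 90)
    res <- list(frequencies = freqs, mean = mo$mean,
                lower = pi_$lower, upper = pi_$upper, sobol = mo$sobol,
                n_evals = n_nodes, method = "pc", parameters = nm,
                seed = study$seed, surrogate = surr)
  }
  colnames(res$sobol) <- nm
  structure(res, class = "uq_result")
}

#' First-order Sobol indices of a study result
#'
#' @param result a [run_study()] result.
#' @param average average over frequency (the reporting convention when the
#'   indices are frequency-independent)?
#' @return Matrix `n_freq x d`, or a named vector when `average = TRUE`.
#' @export
sobol_first_order <- function(result, average = FALSE) {
  stopifnot(inherits(result, "uq_result"))
  if (average) colMeans(result$sobol) else result$sobol
}

#' @export
print.uq_result <- function(x, ...) {
  cat(sprintf("<uq_result> %s, %d evaluations, %d frequencies\n",
              toupper(x$method), x$n_evals, length(x$frequencies)))
  cat("averaged first-order Sobol indices:\n")
  print(round(colMeans(x$sobol), 3))
  invisible(x)
}
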