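# Independent oracles used across test files.
#
# oracle_cm_multishell solves the concentric-multishell polarisation
# problem from scratch: Laplace dipole potentials phi_j = (B_j r +
# C_j/r^2) cos(theta) in every layer, continuity of potential and of
# normal displacement at every interface, unit external field.  This is a
# direct linear-system solution of the boundary-value problem, fully
# independent of the recursive shell-reduction formula implemented in the
# package.

# radii: increasing interface radii (m); eps: complex permittivity of the
# regions inside each interface (innermost first, length = length(radii));
# eps_med: permittivity of the unbounded medium.  Returns the complex
# dipole (Clausius-Mossotti) factor of the whole assembly.
oracle_cm_multishell <- function(radii, eps, eps_med) {
  n <- length(radii)
  stopifnot(length(eps) == n, all(diff(radii) > 0))
  # nondimensionalise (the CM factor is invariant under both scalings)
  radii <- radii / radii[n]
  scal <- max(Mod(c(eps, eps_med)))
  epsall <- c(eps, eps_med) / scal
  # unknowns: B_1 (core; C_1 = 0), then (B_j, C_j) j = 2..n, then D
  nun <- 2 * n
  A <- matrix(0 + 0i, nun, nun)
  rhs <- rep(0 + 0i, nun)
  col_B <- function(j) if (j == 1) 1L else 2L * (j - 1L)
  col_C <- function(j) 2L * (j - 1L) + 1L   # valid for j >= 2
  row <- 0
  for (j in seq_len(n)) {            # interface at radii[j]: region j | j+1
    R <- radii[j]
    inner_is_last <- FALSE
    # potential continuity
    row <- row + 1
    A[row, col_B(j)] <- R
    if (j > 1) A[row, col_C(j)] <- 1 / R^2
    if (j < n) {
      A[row, col_B(j + 1)] <- -R
      A[row, col_C(j + 1)] <- -1 / R^2
    } else {
      A[row, nun] <- -1 / R^2        # D term
      rhs[row] <- -R                 # from phi_ext = -r + D/r^2
    }
    # normal displacement continuity
    row <- row + 1
    A[row, col_B(j)] <- epsall[j]
    if (j > 1) A[row, col_C(j)] <- -2 * epsall[j] / R^3
    if (j < n) {
      A[row, col_B(j + 1)] <- -epsall[j + 1]
      A[row, col_C(j + 1)] <- 2 * epsall[j + 1] / R^3
    } else {
      A[row, nun] <- 2 * epsall[n + 1] / R^3
      rhs[row] <- -epsall[n + 1]
    }
  }
  x <- solve(A, rhs)
  D <- x[nun]
  D / radii[n]^3
}

# equivalent homogeneous permittivity implied by a CM factor K in a medium
oracle_eps_from_cm <- function(K, eps_med) eps_med * (1 + 2 * K) / (1 - K)

# materials of the printed reference table, used by several files
ref_mats <- function() reference_materials()

# membrane argument used by most FEM tests
ref_membrane <- function(dm = 7e-9)
  list(material = material("m", 0, 11.3), thickness = dm)

# random cell parameter draw from the eukaryotic-range tables
draw_cell_params <- function(n, seed) {
  d <- cm_distributions()
  sample_mc(d, n, seed)
}
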