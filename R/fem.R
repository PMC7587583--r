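# Axisymmetric electro-quasistatic finite elements.
#
# Solves div(kappa grad phi) = 0 in cylindrical (r, z) coordinates with
# kappa = sigma + i omega eps_r eps0 per region, phi = V0 on the outer face
# of the top cover slip, phi = 0 on the bottom one (capacitive coupling:
# the electrodes themselves are not modelled), natural (zero normal
# current) conditions elsewhere, and the symmetry axis at r = 0.  Linear
# (P1) triangles; the axisymmetric weight 2*pi*r is integrated exactly for
# P1 gradients via the centroid radius.  The cell membrane is a thin-layer
# interface: duplicated node pairs coupled by the surface admittance
# Y_m = (sigma_m + i omega eps_m eps0) / d_m, so the pairwise potential
# jump is the transmembrane potential.

#' Precompute the finite-element operators of a mesh
#'
#' Assembles one real stiffness matrix per region (admittivity factored
#' out) plus the membrane interface mass matrix, so that frequency sweeps
#' and material studies reuse the geometric work.
#'
#' @param mesh an `eqs_mesh`.
#' @return An object of class `fem_system`.
#' @export
fem_system <- function(mesh) {
  stopifnot(inherits(mesh, "eqs_mesh"))
  nd <- mesh$nodes; tri <- mesh$tri
  n <- nrow(nd)
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  rbar <- (x1 + x2 + x3) / 3
  w <- 2 * pi * rbar / (2 * area2)   # 2*pi*rbar / (4A)

  tags <- sort(unique(mesh$region))
  K <- vector("list", length(tags)); names(K) <- tags
  for (tag in tags) {
    e <- which(mesh$region == tag)
    ii <- jj <- xx <- vector("list", 9)
    k <- 1
    for (a in 1:3) for (bb in 1:3) {
      ii[[k]] <- tri[e, a]
      jj[[k]] <- tri[e, bb]
      xx[[k]] <- w[e] * (b[e, a] * b[e, bb] + cc[e, a] * cc[e, bb])
      k <- k + 1
    }
    K[[tag]] <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                     x = unlist(xx), dims = c(n, n))
  }

  Mmem <- NULL
  if (!is.null(mesh$membrane)) {
    mb <- mesh$membrane[order(mesh$membrane$theta), ]
    r <- nd[mb$outer, 1]; z <- nd[mb$outer, 2]
    k <- seq_len(nrow(mb) - 1)
    L <- sqrt((r[k + 1] - r[k])^2 + (z[k + 1] - z[k])^2)
    xi <- c(-1, 1) / sqrt(3)
    m11 <- m12 <- m22 <- 0
    for (g in 1:2) {
      N1 <- (1 - xi[g]) / 2; N2 <- (1 + xi[g]) / 2
      rg <- N1 * r[k] + N2 * r[k + 1]
      wq <- 2 * pi * rg * L / 2
      m11 <- m11 + wq * N1 * N1
      m12 <- m12 + wq * N1 * N2
      m22 <- m22 + wq * N2 * N2
    }
    ain <- mb$inner[k]; bin <- mb$inner[k + 1]
    aout <- mb$outer[k]; bout <- mb$outer[k + 1]
    # energy of the jump: + (in,in), + (out,out), - (in,out), - (out,in)
    blk <- function(p, q, s)
      list(i = c(p, p, q, q), j = c(p, q, p, q),
           x = s * c(m11, m12, m12, m22))
    parts <- list(blk(ain, bin, 1), blk(aout, bout, 1),
                  list(i = c(ain, ain, bin, bin),
                       j = c(aout, bout, aout, bout),
                       x = -c(m11, m12, m12, m22)),
                  list(i = c(aout, bout, aout, bout),
                       j = c(ain, ain, bin, bin),
                       x = -c(m11, m12, m12, m22)))
    Mmem <- Matrix::sparseMatrix(i = unlist(lapply(parts, `[[`, "i")),
                                 j = unlist(lapply(parts, `[[`, "j")),
                                 x = unlist(lapply(parts, `[[`, "x")),
                                 dims = c(n, n))
    mesh$membrane <- mb
  }

  structure(list(mesh = mesh, n = n, K = K, Mmem = Mmem,
                 b = b, c = cc, area2 = area2, rbar = rbar),
            class = "fem_system")
}

#' Solve the electro-quasistatic problem at one frequency
#'
#' @param x an `eqs_mesh` or a [fem_system()] (reuse the latter for
#'   sweeps).
#' @param materials named list of [material()] objects, one entry per
#'   region tag of the mesh.
#' @param frequency frequency in Hz (single value).
#' @param V0 applied voltage amplitude in V (top electrode; bottom is 0).
#' @param membrane `NULL`, or `list(material = , thickness = )` describing
#'   the cell membrane; required when the mesh carries a membrane
#'   interface.
#' @return An object of class `eqs_solution` carrying the complex nodal
#'   potential, electrode currents, and per-element complex field.
#' @export
solve_eqs <- function(x, materials, frequency, V0,
                      membrane = NULL) {
  sys <- if (inherits(x, "fem_system")) x else fem_system(x)
  mesh <- sys$mesh
  stopifnot(length(frequency) == 1)
  check_frequency(frequency)
  tags <- names(sys$K)
  missing <- setdiff(tags, names(materials))
  if (length(missing))
    stop("no material given for region(s): ", paste(missing, collapse = ", "))
  if (!is.null(mesh$membrane) && is.null(membrane))
    stop("mesh has a membrane interface; supply 'membrane'")

  n <- sys$n
  Kre <- Kim <- NULL
  for (tag in tags) {
    kap <- admittivity(materials[[tag]], frequency)
    Kre <- if (is.null(Kre)) Re(kap) * sys$K[[tag]] else
      Kre + Re(kap) * sys$K[[tag]]
    Kim <- if (is.null(Kim)) Im(kap) * sys$K[[tag]] else
      Kim + Im(kap) * sys$K[[tag]]
  }
  if (!is.null(sys$Mmem)) {
    Ym <- admittivity(membrane$material, frequency) / membrane$thickness
    Kre <- Kre + Re(Ym) * sys$Mmem
    Kim <- Kim + Im(Ym) * sys$Mmem
  }

  top <- mesh$bc$top; bottom <- mesh$bc$bottom
  if (!length(top) || !length(bottom)) stop("electrode node sets are empty")
  fixed <- c(top, bottom)
  free <- setdiff(seq_len(n), fixed)
  x0 <- numeric(n); x0[top] <- V0
  # real block form of the complex system
  A <- rbind(cbind(Kre, -Kim), cbind(Kim, Kre))
  free2 <- c(free, free + n)
  x0full <- c(x0, numeric(n))
  rhs <- -(A %*% x0full)[free2]
  sol <- Matrix::solve(A[free2, free2, drop = FALSE], rhs)
  phi_re <- x0; phi_im <- numeric(n)
  phi_re[free] <- as.numeric(sol)[seq_along(free)]
  phi_im[free] <- as.numeric(sol)[seq_along(free) + length(free)]
  phi <- complex(real = phi_re, imaginary = phi_im)

  # electrode currents from the discrete reaction forces
  y <- complex(real = as.numeric(Kre %*% phi_re - Kim %*% phi_im),
               imaginary = as.numeric(Kim %*% phi_re + Kre %*% phi_im))
  I_top <- sum(y[top]); I_bottom <- sum(y[bottom])

  # element fields E = -grad(phi)
  tri <- mesh$tri
  p1 <- phi[tri[, 1]]; p2 <- phi[tri[, 2]]; p3 <- phi[tri[, 3]]
  Er <- -(p1 * sys$b[, 1] + p2 * sys$b[, 2] + p3 * sys$b[, 3]) / sys$area2
  Ez <- -(p1 * sys$c[, 1] + p2 * sys$c[, 2] + p3 * sys$c[, 3]) / sys$area2

  structure(list(phi = phi, frequency = frequency, V0 = V0,
                 I_top = I_top, I_bottom = I_bottom,
                 Er = Er, Ez = Ez, system = sys,
                 materials = materials, membrane = membrane),
            class = "eqs_solution")
}

#' @export
print.eqs_solution <- function(x, ...) {
  cat(sprintf("<eqs_solution> f = %g Hz, V0 = %g V, |Z| = %.4g ohm\n",
              x$frequency, x$V0, Mod(fem_impedance(x))))
  invisible(x)
}

#' Chamber impedance from a finite-element solution
#'
#' `Z = V0 / I` with `I` the total complex current through the top
#' electrode, evaluated from the discrete reaction forces (axisymmetric
#' surface integral of the normal current density).
#'
#' @param solution an `eqs_solution`.
#' @return Complex impedance in ohm.
#' @export
fem_impedance <- function(solution) {
  stopifnot(inherits(solution, "eqs_solution"))
  if (Mod(solution$I_top) == 0) stop("zero electrode current")
  solution$V0 / solution$I_top
}

#' Field statistics over a region
#'
#' Volume-weighted mean and maximum of the complex field magnitude
#' \eqn{|E| = \sqrt{|E_r|^2 + |E_z|^2}} over all elements of a region,
#' optionally restricted to a bounding box.
#'
#' @param solution an `eqs_solution`.
#' @param region region tag (character) or vector of tags.
#' @param bbox optional `list(r = c(min, max), z = c(min, max))` filter on
#'   element centroids.
#' @return `list(mean, max, n_elements)`, fields in V/m.
#' @export
probe_field <- function(solution, region, bbox = NULL) {
  stopifnot(inherits(solution, "eqs_solution"))
  sys <- solution$system; mesh <- sys$mesh
  sel <- mesh$region %in% region
  if (!is.null(bbox)) {
    cen_r <- sys$rbar
    cen_z <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
                mesh$nodes[mesh$tri[, 3], 2]) / 3
    if (!is.null(bbox$r)) sel <- sel & cen_r >= bbox$r[1] & cen_r <= bbox$r[2]
    if (!is.null(bbox$z)) sel <- sel & cen_z >= bbox$z[1] & cen_z <= bbox$z[2]
  }
  if (!any(sel)) stop("empty probe region")
  Emag <- sqrt(Mod(solution$Er[sel])^2 + Mod(solution$Ez[sel])^2)
  w <- sys$rbar[sel] * sys$area2[sel]   # ~ 2*pi*r*A up to a constant
  list(mean = sum(w * Emag) / sum(w), max = max(Emag),
       n_elements = sum(sel))
}

#' Field inside and outside the hydrogel
#'
#' Mean field magnitude over the hydrogel block (`Ei`) and over the
#' surrounding medium at matched height (`Eo`).
#'
#' @param solution an `eqs_solution` of a mesh with a `"hydro"` region.
#' @param r_out radial band (m) in the medium used for `Eo`; defaults to
#'   2--10 mm, inside the spatially uniform part of the chamber.
#' @return `list(Ei, Eo)` in V/m.
#' @export
field_in_out <- function(solution, r_out = c(2e-3, 10e-3)) {
  sys <- solution$system; mesh <- sys$mesh
  if (!any(mesh$region == "hydro")) stop("mesh has no hydrogel region")
  hyd <- mesh$region == "hydro"
  cen_z <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
              mesh$nodes[mesh$tri[, 3], 2]) / 3
  zr <- range(cen_z[hyd])
  Ei <- probe_field(solution, "hydro")$mean
  Eo <- probe_field(solution, "buf", bbox = list(r = r_out, z = zr))$mean
  list(Ei = Ei, Eo = Eo)
}

membrane_pair_at <- function(mesh, theta) {
  mb <- mesh$membrane
  if (is.null(mb)) stop("mesh has no membrane interface")
  mb[which.min(abs(mb$theta - theta)), ]
}

#' Transmembrane potential at a probe point
#'
#' The potential jump `phi_inner - phi_outer` across the thin-layer
#' membrane at the cell apex (`"top"`, towards the top electrode), the
#' equator (`"side"`), or the bottom pole.
#'
#' @param solution an `eqs_solution` of a mesh with a cell.
#' @param probe `"top"`, `"bottom"` or `"side"`.
#' @return Complex transmembrane potential in V.
#' @export
probe_tmp <- function(solution, probe = c("top", "bottom", "side")) {
  probe <- match.arg(probe)
  theta <- c(top = 0, side = pi / 2, bottom = pi)[[probe]]
  pr <- membrane_pair_at(solution$system$mesh, theta)
  solution$phi[pr$inner] - solution$phi[pr$outer]
}

#' Pole-to-equator field ratio around a cell
#'
#' `|E|` just outside the membrane at the top pole divided by `|E|` just
#' outside at the equator, each averaged over the exterior elements
#' touching the respective membrane node.  Values below one mean the side
#' of the cell sees the stronger field; a ratio of one means pole and
#' equator fields match (no preferential squeezing direction).
#'
#' @param solution an `eqs_solution` of a mesh with a cell.
#' @return Dimensionless ratio.
#' @export
field_ratio <- function(solution) {
  sys <- solution$system; mesh <- sys$mesh
  if (is.null(mesh$membrane)) stop("mesh has no membrane interface")
  ext_field_at <- function(theta) {
    node <- membrane_pair_at(mesh, theta)$outer
    e <- which((mesh$tri[, 1] == node | mesh$tri[, 2] == node |
                  mesh$tri[, 3] == node) & mesh$region != "cyt")
    if (!length(e)) stop("probe node has no exterior elements")
    mean(sqrt(Mod(solution$Er[e])^2 + Mod(solution$Ez[e])^2))
  }
  ext_field_at(0) / ext_field_at(pi / 2)
}

#' Sweep the finite-element model over frequency
#'
#' @param x an `eqs_mesh` or [fem_system()].
#' @param materials,V0,membrane as in [solve_eqs()].
#' @param frequencies vector of frequencies in Hz.
#' @param extract function applied to each `eqs_solution`; must return a
#'   named list of scalars.  Defaults to impedance magnitude and phase.
#' @return A `data.frame` with a `frequency_hz` column plus the extracted
#'   quantities.
#' @export
fem_sweep <- function(x, materials, frequencies, V0, membrane = NULL,
                      extract = NULL) {
  sys <- if (inherits(x, "fem_system")) x else fem_system(x)
  if (is.null(extract))
    extract <- function(sol) {
      Z <- fem_impedance(sol)
      list(z_abs_ohm = Mod(Z), z_phase_deg = Arg(Z) * 180 / pi)
    }
  rows <- lapply(frequencies, function(f) {
    sol <- solve_eqs(sys, materials, f, V0, membrane = membrane)
    c(list(frequency_hz = f), extract(sol))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
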