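# Axisymmetric (r, z) triangular meshes for the stimulation chamber.
#
# Two building blocks:
#   * graded tensor-product grids of rectangles split into triangles, for
#     the layered chamber (+ optional hydrogel block / dish ring);
#   * an O-grid around a spherical or oblate cell: a polar core inside the
#     membrane, a transfinite transition ring from the membrane curve to a
#     rectangular hole cut out of the tensor grid.
# The nm-thick membrane is not meshed volumetrically; the membrane curve
# carries duplicated nodes (inner/outer copies) that the solver couples
# through a surface admittance, so the potential jump across the pair IS
# the transmembrane potential.

#' One-sided graded 1D point set
#'
#' Points from `x0` to `x1` whose spacing starts at `h0` next to `x0` and
#' grows geometrically (factor `ratio`) up to `hmax`.  The final interval is
#' adjusted to land exactly on `x1`.
#'
#' @param x0,x1 interval ends, `x1 > x0`.
#' @param h0 first spacing at `x0`.
#' @param hmax spacing cap.
#' @param ratio geometric growth factor.
#' @return Increasing numeric vector including both end points.
#' @keywords internal
grade_span <- function(x0, x1, h0, hmax = Inf, ratio = 1.4) {
  L <- x1 - x0
  stopifnot(L > 0, h0 > 0, ratio > 1)
  if (h0 >= L) return(c(x0, x1))
  sp <- numeric(0); s <- 0; h <- h0
  while (s + h < L) {
    sp <- c(sp, h); s <- s + h
    h <- min(h * ratio, hmax)
  }
  sp <- c(sp, L - s)
  n <- length(sp)
  if (n > 1 && sp[n] < 0.45 * sp[n - 1]) {
    sp[n - 1] <- sp[n - 1] + sp[n]
    sp <- sp[-n]
  }
  x0 + c(0, cumsum(sp))
}

# graded points approaching x1 with fine spacing h1 at x1
grade_span_to <- function(x0, x1, h1, hmax = Inf, ratio = 1.4) {
  rev(x1 - (grade_span(0, x1 - x0, h1, hmax, ratio) - 0))
}

dedupe_lines <- function(x, tol) {
  x <- sort(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

#' Build an axisymmetric triangular mesh
#'
#' Tensor-product grid over `rlines` x `zlines` with elements tagged by
#' `region_fn`, optionally with an O-grid cell inserted (rectangular hole +
#' transition ring + polar core + duplicated membrane nodes).
#'
#' @param rlines,zlines grid lines in m (r >= 0).  When a `cell` is given,
#'   the caller supplies lines outside the hole only; hole lines are added
#'   internally.
#' @param region_fn `function(r, z)` mapping element centroids to region
#'   tags (character).
#' @param cell optional list describing the embedded cell:
#'   `zc` (centre height), `a_r`, `a_z` (semi-axes), `S_r`, `S_z`
#'   (hole half-widths, `S_r >= a_r`, `S_z >= a_z`), `m_r`, `m_z`
#'   (hole edge subdivisions), `n_core`, `n_trans` (radial layers inside /
#'   outside the membrane), `region` (interior tag, default `"cyt"`).
#' @param electrode_radius Dirichlet electrodes span `r <=` this value on
#'   the bottom (`z = min`) and top (`z = max`) boundaries.
#' @return An object of class `eqs_mesh`: `nodes` (N x 2), `tri` (M x 3),
#'   `region` (tag per element), `bc` (node index lists `top`, `bottom`),
#'   `membrane` (data frame `inner`, `outer`, `theta` or `NULL`).
#' @export
mesh_axisym <- function(rlines, zlines, region_fn, cell = NULL,
                        electrode_radius = Inf) {
  tolr <- 1e-9 * max(rlines)
  tolz <- 1e-9 * (max(zlines) - min(zlines))
  if (!is.null(cell)) {
    cl <- cell
    cl$region <- cl$region %||% "cyt"
    stopifnot(cl$S_r >= cl$a_r, cl$S_z >= cl$a_z,
              cl$m_r >= 2, cl$m_z >= 2, cl$n_core >= 2, cl$n_trans >= 2)
    rlines <- c(seq(0, cl$S_r, length.out = cl$m_r + 1),
                rlines[rlines > cl$S_r + tolr])
    zhole <- seq(cl$zc - cl$S_z, cl$zc + cl$S_z, length.out = 2 * cl$m_z + 1)
    zlines <- c(zhole,
                zlines[zlines < cl$zc - cl$S_z - tolz |
                       zlines > cl$zc + cl$S_z + tolz])
  }
  rl <- dedupe_lines(rlines, tolr)
  zl <- dedupe_lines(zlines, tolz)
  nr <- length(rl); nz <- length(zl)

  in_hole_strict <- function(r, z) {
    if (is.null(cell)) return(rep(FALSE, length(r)))
    r < cell$S_r - tolr & abs(z - cell$zc) < cell$S_z - tolz
  }

  grid_r <- rep(rl, times = nz)
  grid_z <- rep(zl, each = nr)
  keep <- !in_hole_strict(grid_r, grid_z)
  node_id <- integer(nr * nz)
  node_id[keep] <- seq_len(sum(keep))
  nodes <- cbind(r = grid_r[keep], z = grid_z[keep])

  gid <- function(i, j) node_id[(j - 1L) * nr + i]

  # tensor elements (skip rectangles inside the hole)
  tri <- NULL
  ii <- rep(seq_len(nr - 1), times = nz - 1)
  jj <- rep(seq_len(nz - 1), each = nr - 1)
  rc <- (rl[ii] + rl[ii + 1]) / 2
  zc_ <- (zl[jj] + zl[jj + 1]) / 2
  use <- !in_hole_strict(rc, zc_)
  n1 <- gid(ii[use], jj[use]);     n2 <- gid(ii[use] + 1L, jj[use])
  n3 <- gid(ii[use] + 1L, jj[use] + 1L); n4 <- gid(ii[use], jj[use] + 1L)
  tri <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))

  membrane <- NULL
  if (!is.null(cell)) {
    cl <- cell
    # ordered hole-perimeter tensor nodes, from (0, zc+S_z) to (0, zc-S_z)
    i_S <- which(abs(rl - cl$S_r) <= tolr)
    j_top <- which(abs(zl - (cl$zc + cl$S_z)) <= tolz)
    j_bot <- which(abs(zl - (cl$zc - cl$S_z)) <= tolz)
    i_top <- which(rl <= cl$S_r + tolr)                    # r = 0 .. S_r
    j_side <- which(zl >= cl$zc - cl$S_z - tolz & zl <= cl$zc + cl$S_z + tolz)
    per_i <- c(i_top, rep(i_S, length(j_side) - 1L), rev(i_top)[-1])
    per_j <- c(rep(j_top, length(i_top)), rev(j_side)[-1],
               rep(j_bot, length(i_top) - 1L))
    per_id <- gid(per_i, per_j)
    pr <- rl[per_i]; pz <- zl[per_j]
    theta <- atan2(pr / cl$S_r, (pz - cl$zc) / cl$S_z)
    theta[1] <- 0; theta[length(theta)] <- pi
    nth <- length(theta)

    new_node <- function(r, z) {
      nodes <<- rbind(nodes, cbind(r = r, z = z))
      nrow(nodes)
    }
    ring_nodes <- function(s) {  # scaled membrane-curve ring, s in (0, 1]
      r <- cl$a_r * s * sin(theta)
      z <- cl$zc + cl$a_z * s * cos(theta)
      r[c(1, nth)] <- 0
      vapply(seq_len(nth), function(k) new_node(r[k], z[k]), integer(1))
    }

    # transition: membrane curve (t = 0, new nodes) -> hole perimeter
    g <- 1.35
    tgrid <- (g^(0:cl$n_trans) - 1) / (g^cl$n_trans - 1)
    er <- cl$a_r * sin(theta); ez <- cl$zc + cl$a_z * cos(theta)
    er[c(1, nth)] <- 0
    rings <- vector("list", cl$n_trans + 1)
    rings[[1]] <- ring_nodes(1)                     # outer membrane copies
    outer_ids <- rings[[1]]
    if (cl$n_trans > 1)
      for (l in 2:cl$n_trans) {
        t <- tgrid[l]
        r <- (1 - t) * er + t * pr
        z <- (1 - t) * ez + t * pz
        r[c(1, nth)] <- 0
        rings[[l]] <- vapply(seq_len(nth),
                             function(k) new_node(r[k], z[k]), integer(1))
      }
    rings[[cl$n_trans + 1]] <- per_id
    for (l in seq_len(cl$n_trans)) {
      a <- rings[[l]]; b <- rings[[l + 1]]
      k <- seq_len(nth - 1)
      tri <- rbind(tri,
                   cbind(a[k], b[k], b[k + 1]),
                   cbind(a[k], b[k + 1], a[k + 1]))
    }

    # core: centre + rings up to the inner membrane copies (s = 1)
    centre <- new_node(0, cl$zc)
    core <- vector("list", cl$n_core)
    for (i in seq_len(cl$n_core)) core[[i]] <- ring_nodes(i / cl$n_core)
    inner_ids <- core[[cl$n_core]]
    k <- seq_len(nth - 1)
    tri <- rbind(tri, cbind(rep(centre, nth - 1), core[[1]][k],
                            core[[1]][k + 1]))
    if (cl$n_core > 1)
      for (i in seq_len(cl$n_core - 1)) {
        a <- core[[i]]; b <- core[[i + 1]]
        tri <- rbind(tri,
                     cbind(a[k], b[k], b[k + 1]),
                     cbind(a[k], b[k + 1], a[k + 1]))
      }
    membrane <- data.frame(inner = inner_ids, outer = outer_ids,
                           theta = theta)
  }

  # orientation + degenerate-element guard
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- a2 < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  degen <- abs(a2) <= 0
  if (any(degen)) tri <- tri[!degen, , drop = FALSE]

  cen_r <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cen_z <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  region <- region_fn(cen_r, cen_z)
  if (!is.null(cell)) {
    # interior of the membrane curve: cytoplasm, regardless of region_fn
    inside <- ((cen_r / cell$a_r)^2 +
               ((cen_z - cell$zc) / cell$a_z)^2) < 1
    region[inside] <- cell$region %||% "cyt"
  }

  zmin <- min(zl); zmax <- max(zl)
  er <- electrode_radius * (1 + 1e-9)
  on_bot <- abs(nodes[, 2] - zmin) <= tolz & nodes[, 1] <= er
  on_top <- abs(nodes[, 2] - zmax) <= tolz & nodes[, 1] <= er
  structure(list(nodes = nodes, tri = tri, region = region,
                 bc = list(top = which(on_top), bottom = which(on_bot)),
                 membrane = membrane),
            class = "eqs_mesh")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eqs_mesh <- function(x, ...) {
  cat(sprintf("<eqs_mesh> %d nodes, %d triangles, regions: %s%s\n",
              nrow(x$nodes), nrow(x$tri),
              paste(sort(unique(x$region)), collapse = ", "),
              if (is.null(x$membrane)) ""
              else sprintf(" (membrane interface, %d node pairs)",
                           nrow(x$membrane))))
  invisible(x)
}

# ---- scenario meshers -------------------------------------------------

chamber_region_fn <- function(stack, hydrogel = NULL, dish_radius = NULL) {
  dcs <- stack$cover_slip$d
  ztop <- dcs + stack$buffer$d
  rcs <- stack$cover_slip$r
  force(hydrogel)
  function(r, z) {
    tag <- ifelse(z < dcs, "cs_bot", ifelse(z > ztop, "cs_top", "buf"))
    if (!is.null(hydrogel))
      tag[tag == "buf" & r < hydrogel$radius &
            z < dcs + hydrogel$height] <- "hydro"
    if (!is.null(dish_radius)) tag[r > rcs] <- "ins"
    tag
  }
}

#' Mesh the layered chamber (no cell)
#'
#' Simplified parallel-plate geometry: bottom cover slip, medium, top cover
#' slip, optionally with the hydrogel block (1 mm x 1 mm by default) on the
#' bottom cover slip at the symmetry axis, and optionally an annular plastic
#' dish ring outside the cover-slip radius.
#'
#' @param stack a [chamber_stack()].
#' @param hydrogel `NULL`, or `list(radius, height)` in m.
#' @param dish_radius `NULL`, or outer radius in m of a plastic ("ins")
#'   annulus filling `r > r_cs`.
#' @param refinement non-negative integer; each level halves target element
#'   sizes.
#' @return An `eqs_mesh`.
#' @export
mesh_stack <- function(stack, hydrogel = NULL, dish_radius = NULL,
                       refinement = 0) {
  f <- 2^refinement
  dcs <- stack$cover_slip$d; dbuf <- stack$buffer$d
  rcs <- stack$cover_slip$r
  rmax <- dish_radius %||% rcs
  zl <- c(seq(0, dcs, length.out = 3 * f + 1),
          seq(dcs, dcs + dbuf, length.out = 10 * f + 1),
          seq(dcs + dbuf, 2 * dcs + dbuf, length.out = 3 * f + 1))
  rl <- seq(0, rmax, length.out = 20 * f + 1)
  if (!is.null(hydrogel)) {
    zl <- c(zl, seq(dcs, dcs + hydrogel$height, length.out = 8 * f + 1))
    # refine towards the hydrogel edge from both sides
    he <- hydrogel$radius
    rl <- c(grade_span_to(0, he, h1 = he / (10 * f), hmax = rcs / (12 * f)),
            grade_span(he, rmax, h0 = he / (10 * f), hmax = rcs / (12 * f)))
  }
  if (!is.null(dish_radius)) rl <- c(rl, rcs)
  mesh_axisym(rl, zl, chamber_region_fn(stack, hydrogel, dish_radius),
              electrode_radius = rcs)
}

#' Mesh a uniform-field box containing one cell
#'
#' Validation fixture: a cylindrical box of a single medium with Dirichlet
#' electrodes on top and bottom faces and a spherical (or oblate) cell at
#' the centre of the axis.  Used to compare the finite-element
#' transmembrane potential against the analytic first-order closed form.
#'
#' @param box_height,box_radius box dimensions in m.
#' @param a_r,a_z cell semi-axes in m (equal for a sphere).
#' @param refinement non-negative integer, halves element sizes per level.
#' @return An `eqs_mesh` with regions `"med"` and `"cyt"`.
#' @export
mesh_box_cell <- function(box_height = 100e-6, box_radius = 100e-6,
                          a_r = 5e-6, a_z = 5e-6, refinement = 0) {
  f <- 2^refinement
  zc <- box_height / 2
  S_r <- 2 * a_r; S_z <- 2 * a_z
  m_r <- 12 * f; m_z <- 12 * f
  h0 <- S_r / m_r
  cell <- list(zc = zc, a_r = a_r, a_z = a_z, S_r = S_r, S_z = S_z,
               m_r = m_r, m_z = m_z, n_core = 8 * f, n_trans = 8 * f)
  rl <- grade_span(S_r, box_radius, h0 = h0, hmax = box_radius / (6 * f))
  zl <- c(grade_span_to(0, zc - S_z, h1 = h0, hmax = box_height / (8 * f)),
          grade_span(zc + S_z, box_height, h0 = h0,
                     hmax = box_height / (8 * f)))
  mesh_axisym(rl, zl, function(r, z) rep("med", length(r)), cell = cell)
}

#' Mesh the chamber with hydrogel and a single cell
#'
#' Full study geometry: layered chamber, hydrogel block, and one cell whose
#' placement follows the experimental configurations -- an oblate adherent
#' cell on the bottom cover slip (2D benchmark), the same cell resting on
#' the hydrogel surface, a spherical cell straddling the hydrogel--medium
#' interface, or a spherical cell centred in the hydrogel.
#'
#' @param stack a [chamber_stack()].
#' @param hydrogel `list(radius, height)` in m, or `NULL` (benchmark only).
#' @param placement one of `"adherent_bottom"`, `"elliptical_on_hydrogel"`,
#'   `"spherical_on_hydrogel_interface"`, `"spherical_centred_in_hydrogel"`.
#' @param a_r,a_z cell semi-axes in m.
#' @param refinement non-negative integer.
#' @return An `eqs_mesh` with a membrane interface.
#' @export
mesh_chamber_cell <- function(stack, hydrogel = NULL,
                              placement = c("adherent_bottom",
                                            "elliptical_on_hydrogel",
                                            "spherical_on_hydrogel_interface",
                                            "spherical_centred_in_hydrogel"),
                              a_r = 5e-6, a_z = 5e-6, refinement = 0) {
  placement <- match.arg(placement)
  f <- 2^refinement
  dcs <- stack$cover_slip$d; dbuf <- stack$buffer$d
  rcs <- stack$cover_slip$r
  ztop <- dcs + dbuf; zmax <- ztop + dcs
  zh <- if (!is.null(hydrogel)) dcs + hydrogel$height else NA_real_
  if (placement != "adherent_bottom" && is.null(hydrogel))
    stop("placement '", placement, "' requires a hydrogel block")

  if (placement == "adherent_bottom") {
    # stand-off of one radial semi-axis keeps the cell in the locally
    # uniform field just above the substrate (an insulating wall right at
    # the membrane would skew the apex/bottom comparison)
    zc <- dcs + a_r + a_z; S_z <- a_r + a_z
  } else if (placement == "elliptical_on_hydrogel") {
    # tangent contact: the bottom membrane pole touches the gel surface
    zc <- zh + a_z; S_z <- 2 * a_z
  } else if (placement == "spherical_on_hydrogel_interface") {
    zc <- zh; S_z <- 2 * a_z
  } else {
    zc <- dcs + hydrogel$height / 2; S_z <- 2 * a_z
  }
  S_r <- 2 * a_r
  m_r <- max(6, round(8 * S_r / 10e-6)) * f
  m_z <- 2 * max(3, round(4 * S_z / 10e-6)) * f
  h0 <- max(S_r / m_r, S_z / m_z)
  cell <- list(zc = zc, a_r = a_r, a_z = a_z, S_r = S_r, S_z = S_z,
               m_r = m_r, m_z = m_z, n_core = 6 * f, n_trans = 6 * f)

  hmid <- if (!is.null(hydrogel)) hydrogel$height / (6 * f) else dbuf / (8 * f)
  hfar <- rcs / (12 * f)
  zl <- c(seq(0, dcs, length.out = 3 * f + 1),
          seq(ztop, zmax, length.out = 3 * f + 1))
  below <- zc - S_z; above <- zc + S_z
  if (below > dcs + 1e-12)
    zl <- c(zl, grade_span_to(dcs, below, h1 = h0, hmax = hmid))
  if (!is.na(zh)) {
    if (above < zh - 1e-12)
      zl <- c(zl, grade_span(above, zh, h0 = h0, hmax = hmid),
              grade_span(zh, ztop, h0 = hmid, hmax = dbuf / (4 * f)))
    else
      zl <- c(zl, grade_span(above, ztop, h0 = h0, hmax = dbuf / (4 * f)))
    if (below > zh + 1e-12)   # cell fully above the hydrogel surface
      zl <- c(zl, zh)
  } else {
    zl <- c(zl, grade_span(above, ztop, h0 = h0, hmax = dbuf / (4 * f)))
  }
  rl <- grade_span(S_r, rcs, h0 = h0, hmax = hfar)
  if (!is.null(hydrogel)) rl <- c(rl, hydrogel$radius)

  mesh_axisym(rl, zl, chamber_region_fn(stack, hydrogel),
              cell = cell, electrode_radius = rcs)
}
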