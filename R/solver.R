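#' Luminal load specification
#'
#' @param P luminal pressure (kPa), applied as a normal traction on the
#'   lumen boundary. Default 14.6 kPa.
#' @param waveform_scale optional dimensionless scale factor applied to
#'   \code{P} (used by the quasi-static pulsatile envelope).
#' @return an object of class \code{load_spec}.
#' @export
load_spec <- function(P = 14.6, waveform_scale = 1) {
  if (P < 0) stop("invalid-parameter: luminal pressure must be >= 0")
  structure(list(P = P * waveform_scale, waveform_scale = waveform_scale),
            class = "load_spec")
}

#' Solve linear plane-stress equilibrium on a labeled mesh
#'
#' Assembles the orthotropic small-strain stiffness (quadratic triangles,
#' 3-point Gauss) with each element's material axes oriented radially from
#' the arterial centre, applies the luminal pressure as a consistent normal
#' traction on the lumen edges, constrains the symmetry line in its normal
#' direction, pins one outer-wall node on the symmetry line along the
#' symmetry axis to remove the residual rigid mode, and solves the sparse
#' system by direct Cholesky factorization.
#'
#' @param mesh a \code{labeled_mesh}.
#' @param materials named list of \code{tissue_properties} covering every
#'   region label present in the mesh (see \code{\link{default_materials}}).
#' @param load a \code{load_spec}.
#' @param plane \code{"stress"} (default) or \code{"strain"}.
#' @return an object of class \code{plaque_solution}: nodal displacements
#'   (mm), Gauss-point stress/strain components (kPa), the relative residual
#'   of the linear system, and constraint reactions.
#' @export
solve_plane_stress <- function(mesh, materials, load = load_spec(),
                               plane = c("stress", "strain")) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(load, "load_spec"))
  plane <- match.arg(plane)
  regs <- unique(mesh$region)
  miss <- setdiff(regs, names(materials))
  if (length(miss))
    stop("solver error: no material for region(s) ",
         paste(miss, collapse = ", "))

  ## local stiffness per region, rotated per element to radial axes taken
  ## from the arterial (outer-wall) centre
  Dl_by_reg <- lapply(materials[regs], function(t)
    as.vector(plane_stress_matrix(t, 0, plane)$D_local))
  Dloc <- do.call(rbind, Dl_by_reg[mesh$region])
  xc <- rowMeans(matrix(mesh$nodes[mesh$elems[, 1:3], 1], ncol = 3))
  yc <- rowMeans(matrix(mesh$nodes[mesh$elems[, 1:3], 2], ncol = 3))
  phi <- atan2(yc, xc)
  Dg <- fem_rotate_D(Dloc, phi)

  trip <- fem_assemble(mesh$nodes, mesh$elems, Dg)
  ndof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(ndof, ndof))

  f <- lumen_pressure_load(mesh, load$P)

  fixed <- constrained_dofs(mesh)
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  if (load$P != 0) {
    Kff <- Matrix::forceSymmetric(K[free, free])
    uf <- tryCatch(
      as.vector(Matrix::solve(Kff, f[free])),
      error = function(e)
        stop("solver error: singular or non-positive-definite system (",
             conditionMessage(e), ")"))
    u[free] <- uf
  }
  res_vec <- as.vector(K %*% u - f)
  fn <- sqrt(sum(f^2))
  residual <- if (fn > 0) sqrt(sum(res_vec[free]^2)) / fn else 0
  reactions <- res_vec[fixed]

  st <- fem_stress(mesh$nodes, mesh$elems, Dg, u)

  ## report displacements in the zero-net-translation frame: the rigid
  ## x-translation left free by the symmetry constraints is removed by
  ## subtracting the area-weighted mean (stresses are unaffected)
  aw <- rep(element_areas(mesh) / 6, 6)
  nw <- tapply(aw, as.vector(mesh$elems), sum)
  nidx <- as.integer(names(nw))
  um <- matrix(u, ncol = 2, byrow = TRUE)
  um[, 1] <- um[, 1] - sum(nw * um[nidx, 1]) / sum(nw)
  if (!isTRUE(mesh$half))
    um[, 2] <- um[, 2] - sum(nw * um[nidx, 2]) / sum(nw)
  structure(list(
    u = um,
    stress_gp = st$stress, strain_gp = st$strain, gp_xy = st$gp_xy,
    mesh = mesh, load = load, plane = plane,
    residual = residual,
    reactions = list(dofs = fixed, values = reactions)
  ), class = "plaque_solution")
}

#' @exportS3Method base::print
print.plaque_solution <- function(x, ...) {
  cat(sprintf("plaque_solution: %d nodes, P = %g kPa, residual %.2e\n",
              nrow(x$u), x$load$P, x$residual))
  cat(sprintf("  max |u| = %.4g mm\n", max(sqrt(rowSums(x$u^2)))))
  invisible(x)
}

## consistent nodal loads for a constant pressure on quadratic lumen edges,
## integrated with 3-point Gauss along the (possibly curved) edge
lumen_pressure_load <- function(mesh, P) {
  ndof <- 2L * nrow(mesh$nodes)
  f <- numeric(ndof)
  if (P == 0) return(f)
  ed <- mesh$boundary$lumen
  ctr <- mesh$lumen_center
  xi <- c(0.5 - sqrt(3 / 20), 0.5, 0.5 + sqrt(3 / 20))
  w <- c(5, 8, 5) / 18
  x1 <- mesh$nodes[ed[, 1], 1]; y1 <- mesh$nodes[ed[, 1], 2]
  xm <- mesh$nodes[ed[, 2], 1]; ym <- mesh$nodes[ed[, 2], 2]
  x2 <- mesh$nodes[ed[, 3], 1]; y2 <- mesh$nodes[ed[, 3], 2]
  for (g in 1:3) {
    s <- xi[g]
    N <- c((1 - s) * (1 - 2 * s), 4 * s * (1 - s), s * (2 * s - 1))
    dN <- c(4 * s - 3, 4 - 8 * s, 4 * s - 1)
    gx <- N[1] * x1 + N[2] * xm + N[3] * x2
    gy <- N[1] * y1 + N[2] * ym + N[3] * y2
    tx <- dN[1] * x1 + dN[2] * xm + dN[3] * x2
    ty <- dN[1] * y1 + dN[2] * ym + dN[3] * y2
    nx <- ty; ny <- -tx                    # |t| d_xi = ds, unnormalized
    flip <- (nx * (gx - ctr[1]) + ny * (gy - ctr[2])) < 0
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
    for (a in 1:3) {
      dx <- 2L * ed[, a] - 1L
      fx <- P * w[g] * N[a] * nx
      fy <- P * w[g] * N[a] * ny
      f[dx] <- f[dx] + fx
      f[dx + 1L] <- f[dx + 1L] + fy
    }
  }
  f
}

## symmetry-line and rigid-mode constraints (1-based dof indices)
constrained_dofs <- function(mesh) {
  on_axis <- which(mesh$nodes[, 2] == 0)
  outer_nodes <- unique(as.vector(mesh$boundary$outer_wall))
  axis_outer <- intersect(on_axis, outer_nodes)
  if (!length(axis_outer))
    stop("solver error: no outer-wall node on the symmetry line to pin")
  pin <- axis_outer[which.min(mesh$nodes[axis_outer, 1])]
  if (isTRUE(mesh$half)) {
    ## normal (y) constraint along the whole symmetry line + one axial pin
    sort(unique(c(2L * on_axis, 2L * pin - 1L)))
  } else {
    ## full model: remove the three rigid modes only
    pin2 <- axis_outer[which.max(mesh$nodes[axis_outer, 1])]
    sort(unique(c(2L * pin, 2L * pin2, 2L * pin - 1L)))
  }
}

#' Global equilibrium check
#'
#' Sum of applied loads and constraint reactions, per direction; both
#' components should vanish to roundoff for a converged solve.
#'
#' @param sol a \code{plaque_solution}.
#' @return named numeric: net force residual (x, y) relative to the total
#'   applied load magnitude.
#' @export
equilibrium_residual <- function(sol) {
  f <- lumen_pressure_load(sol$mesh, sol$load$P)
  net <- c(x = sum(f[seq(1, length(f), 2)]), y = sum(f[seq(2, length(f), 2)]))
  dofs <- sol$reactions$dofs
  rx <- sum(sol$reactions$values[dofs %% 2 == 1])
  ry <- sum(sol$reactions$values[dofs %% 2 == 0])
  tot <- sum(abs(f))
  if (tot == 0) tot <- 1
  c(x = (net[["x"]] + rx) / tot, y = (net[["y"]] + ry) / tot)
}
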