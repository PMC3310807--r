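#' Generate a labeled quadratic-triangle mesh of the half cross-section
#'
#' Meshes the half model with a structured mapped grid in lumen-polar
#' coordinates (the solid domain is star-shaped about the lumen centre), so
#' all material interfaces are represented exactly and meshing is
#' deterministic. Six-node (quadratic) triangles are used; midside nodes lie
#' on the parametric surface, so circular boundaries are curved
#' isoparametrically. Resolution is region-aware: the fibrous cap and the
#' calcification gap always carry at least three elements through their
#' thickness, the angular density adapts to the thinnest crescent layer, and
#' the fibrous bulk is graded geometrically away from the lumen.
#'
#' @param regions a \code{plaque_regions} object from
#'   \code{\link{build_cross_section}}.
#' @param level mesh refinement level: \code{"coarse"}, \code{"medium"} or
#'   \code{"fine"}.
#' @param density optional numeric density multiplier overriding the level
#'   presets (coarse 0.35, medium 0.75, fine 1); intended for convergence
#'   studies beyond the standard levels.
#' @return an object of class \code{labeled_mesh}: node coordinates (mm),
#'   six-node triangles, per-element region labels (\code{ndw}, \code{ft},
#'   \code{lp}, \code{cag}) with a logical fibrous-cap flag, and boundary
#'   edge tables tagged \code{lumen}, \code{outer_wall}, \code{symmetry}.
#' @export
generate_mesh <- function(regions, level = c("medium", "coarse", "fine"),
                          density = NULL) {
  stopifnot(inherits(regions, "plaque_regions"))
  level <- match.arg(level)
  dens <- if (is.null(density)) {
    c(coarse = 0.35, medium = 0.75, fine = 1)[[level]]
  } else {
    stopifnot(is.numeric(density), density > 0)
    density
  }
  sp <- regions$spec
  rl <- regions$rl; cx <- regions$cx
  has_lip <- isTRUE(sp$has_lipid)
  annulus <- regions$annulus

  uniform_frac <- function(n) seq(0, 1, length.out = n + 1)
  ## geometric grading with a fixed last/first layer-size ratio, so the
  ## size structure is stable under refinement
  graded_frac <- function(n, total_ratio) {
    if (n == 1) return(c(0, 1))
    q <- total_ratio^(1 / (n - 1))
    s <- q^(0:(n - 1))
    c(0, cumsum(s)) / sum(s)
  }

  ## ---- radial blocks (inner to outer) ------------------------------------
  blocks <- list()
  if (annulus) {
    nw <- max(3, round(12 * dens))
    blocks$wall <- list(label = "ndw", cap = FALSE, n = nw,
                        frac = uniform_frac(nw), kind = "wall")
  } else if (!has_lip) {
    nf <- max(6, round(36 * dens))
    blocks$fibrous <- list(label = "ft", cap = FALSE, n = nf,
                           frac = graded_frac(nf, 10),
                           kind = "fill", r_in = rl)
    nw <- max(2, round(4 * dens))
    blocks$wall <- list(label = "ndw", cap = FALSE, n = nw,
                        frac = uniform_frac(nw), kind = "wall")
  } else {
    a0 <- rl + sp$d_fc
    gap <- if (sp$calcified) sp$d_cg else sp$lipid_thickness
    b0 <- a0 + sp$lipid_thickness
    tiny <- 1e-7 * regions$r_int
    nc <- max(3, floor(3 + 2 * dens))
    blocks$cap <- list(label = "ft", cap = TRUE, n = nc,
                       frac = uniform_frac(nc), kind = "crescent",
                       r_in = rl, r_out = a0)
    if (gap > 0) {
      if (gap < tiny)
        stop("meshing error: region 'lipid' is a degenerate sliver")
      ng <- max(3, round(12 * dens * min(1, gap / 0.35)))
      blocks$lipid <- list(label = "lp", cap = FALSE, n = ng,
                           frac = uniform_frac(ng), kind = "crescent",
                           r_in = a0, r_out = a0 + gap)
    }
    if (sp$calcified && sp$d_cag > 0) {
      if (sp$d_cag < tiny)
        stop("meshing error: region 'cag' is a degenerate sliver")
      na <- max(3, round(10 * dens * min(1, sp$d_cag / 0.33)))
      blocks$cag <- list(label = "cag", cap = FALSE, n = na,
                         frac = uniform_frac(na), kind = "crescent",
                         r_in = a0 + gap, r_out = b0)
    }
    nf <- max(4, round(16 * dens))
    blocks$fibrous <- list(label = "ft", cap = FALSE, n = nf,
                           kind = "fill", r_in = b0)
    nw <- max(2, round(4 * dens))
    blocks$wall <- list(label = "ndw", cap = FALSE, n = nw,
                        frac = uniform_frac(nw), kind = "wall")
  }

  ## ---- angular grid ------------------------------------------------------
  ## element aspect ratios are held near or below ~3.2 in both directions:
  ## the angular step follows the thinnest crescent layer, thick crescent
  ## blocks are subdivided to match, and the graded fibrous bulk grows no
  ## faster than the local arc length allows
  aspect_max <- 2.6
  if (has_lip) {
    theta_s <- regions$theta_s
    ss <- pi - theta_s
    ns <- max(12, round(64 * dens))
    for (b in blocks) {
      if (b$kind != "crescent") next
      t_layer <- (b$r_out - b$r_in) / b$n
      rm <- (b$r_in + b$r_out) / 2
      ns <- max(ns, ceiling(ss / (aspect_max * t_layer / rm)))
    }
    ns <- min(ns, max(160, round(160 * dens)))
    dth <- ss / ns
    ## thick crescent blocks get extra through-thickness layers so their
    ## elements are not sliver-wide at the refined angular step
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (b$kind != "crescent") next
      need <- ceiling((b$r_out - b$r_in) / (aspect_max * dth * b$r_in))
      if (need > b$n) {
        blocks[[nm]]$n <- need
        blocks[[nm]]$frac <- uniform_frac(need)
      }
    }
    ## wall layers follow the angular step so they cannot go sliver-wide
    needw <- ceiling((regions$r_ext - regions$r_int) /
                       (aspect_max * dth * regions$r_int))
    if (needw > blocks$wall$n) {
      blocks$wall$n <- needw
      blocks$wall$frac <- uniform_frac(needw)
    }
    ## fibrous bulk: graded outward, last layer bounded by the outer arc
    Tmax <- internal_radius_at(pi, sp) - b0
    repeat {
      fr <- graded_frac(blocks$fibrous$n, 6)
      last <- Tmax * (fr[length(fr)] - fr[length(fr) - 1])
      if (last <= aspect_max * dth * regions$r_int || blocks$fibrous$n > 200)
        break
      blocks$fibrous$n <- blocks$fibrous$n + 1
    }
    blocks$fibrous$frac <- graded_frac(blocks$fibrous$n, 6)
    ## zone outside the crescent: every layer gets an equal share of the
    ## local thickness (count-proportional block boundaries), and the
    ## angular count is clamped so those uniform layers stay within the
    ## aspect bound at both the lumen and the wall
    nbi <- length(blocks) - 1L            # inner (non-wall) blocks
    phys <- vapply(blocks[seq_len(nbi - 1L)], function(b) b$r_out,
                   numeric(1))
    nlay <- vapply(blocks[seq_len(nbi)], function(b) b$n, numeric(1))
    g_bnd <- cumsum(nlay)[seq_len(nbi - 1L)] / sum(nlay)
    T0 <- internal_radius_at(0, sp) - rl
    tA <- T0 / sum(nlay)                  # uniform zone layer size
    tw <- (regions$r_ext - regions$r_int) / blocks$wall$n
    ## angular steps grow geometrically away from the crescent, capped so
    ## the uniform far-zone layers and the wall stay within the aspect bound
    d0 <- ss / ns
    dmax <- min(aspect_max * tA / regions$r_int,
                aspect_max * tw / regions$r_ext)
    dmax <- max(dmax, d0)
    K <- ceiling(0.25 / d0)                # hold the crescent step briefly
    steps <- pmin(d0 * 1.12^pmax(0, 0:1200 - K), dmax)
    ktot <- which(cumsum(steps) >= theta_s)[1]
    steps <- steps[seq_len(ktot)] * (theta_s / sum(steps[seq_len(ktot)]))
    zoneA <- rev(theta_s - c(0, cumsum(steps)))   # 0 ... theta_s
    zoneA[1] <- 0
    theta <- c(zoneA, seq(theta_s, pi, length.out = ns + 1)[-1])
  } else {
    nth <- if (annulus) max(16, round(120 * dens)) else
      max(24, round(160 * dens))
    theta <- seq(0, pi, length.out = nth + 1)
    theta_s <- NA_real_
  }
  n_th <- length(theta) - 1L
  th2 <- numeric(2L * n_th + 1L)
  th2[seq(1, 2 * n_th + 1, by = 2)] <- theta
  th2[seq(2, 2 * n_th, by = 2)] <- (theta[-1] + theta[-(n_th + 1)]) / 2

  ## ---- radial breakpoints per angular station ----------------------------
  Ri <- if (annulus) rep(regions$r_int, length(th2)) else
    internal_radius_at(th2, sp)
  Re <- external_radius_at(th2, sp)
  nb <- length(blocks)
  w <- rep(1, length(th2))                # crescent-zone blend weight
  bp <- matrix(0, nb + 1L, length(th2))   # block boundary radii
  if (annulus) {
    bp[1, ] <- Ri; bp[2, ] <- Re
  } else {
    bp[1, ] <- rl
    bp[nb, ] <- Ri
    bp[nb + 1L, ] <- Re
    if (has_lip && nb > 2) {
      delta <- min(0.9 * theta_s, 1.7)
      tt <- pmin(pmax((th2 - (theta_s - delta)) / delta, 0), 1)
      w <- tt * tt * (3 - 2 * tt)          # smoothstep, 1 at theta_s
      w[th2 >= theta_s] <- 1
      for (k in seq_len(nb - 2L)) {
        ## crescent boundaries that would not fit inside the narrowing wall
        ## start easing inward before the blend weight alone would move them
        ph <- pmin(phys[k], rl + 0.85 * (Ri - rl))
        bp[k + 1L, ] <- w * ph + (1 - w) * (rl + g_bnd[k] * (Ri - rl))
      }
    }
  }
  if (any(diff(bp) <= 0))
    stop("meshing error: radial block boundaries are not strictly increasing")

  ## ---- doubled-resolution node grid --------------------------------------
  frac2 <- function(fr) {   # insert midpoints into a fraction vector
    n <- length(fr) - 1L
    out <- numeric(2L * n + 1L)
    out[seq(1, 2 * n + 1, by = 2)] <- fr
    out[seq(2, 2 * n, by = 2)] <- (fr[-1] + fr[-(n + 1)]) / 2
    out
  }
  rho_rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    f2 <- frac2(blocks[[k]]$frac)
    lo <- bp[k, ]; hi <- bp[k + 1L, ]
    if (has_lip && !annulus && identical(blocks[[k]]$kind, "fill")) {
      ## outside the crescent the fibrous band can be much thinner than at
      ## the apex: morph its internal grading toward uniform there
      f2u <- frac2(uniform_frac(blocks[[k]]$n))
      wf <- w^4                           # leave sector grading quickly
      fmat <- outer(f2, wf) + outer(f2u, 1 - wf)
      rows <- fmat * matrix(hi - lo, nrow(fmat), length(th2), byrow = TRUE) +
        matrix(lo, nrow(fmat), length(th2), byrow = TRUE)
    } else {
      rows <- outer(f2, hi - lo) + matrix(lo, length(f2), length(th2),
                                          byrow = TRUE)
    }
    rho_rows[[k]] <- if (k == 1L) rows else rows[-1L, , drop = FALSE]
  }
  RHO <- do.call(rbind, rho_rows)
  n_r <- (nrow(RHO) - 1L) / 2L            # number of element layers
  CT <- matrix(cos(th2), nrow(RHO), length(th2), byrow = TRUE)
  ST <- matrix(sin(th2), nrow(RHO), length(th2), byrow = TRUE)
  X <- cx + RHO * CT
  Y <- RHO * ST
  Y[abs(Y) < 1e-12] <- 0
  nodes <- cbind(as.vector(X), as.vector(Y))
  nr2 <- nrow(RHO)                        # 2*n_r + 1

  ## ---- elements (two T6 per quad patch, alternating diagonals) -----------
  I <- rep(seq_len(n_r), n_th)
  J <- rep(seq_len(n_th), each = n_r)
  r0 <- 2L * I - 1L; c0 <- 2L * J - 1L
  id <- function(i, j) (j - 1L) * nr2 + i
  A <- id(r0, c0);      B <- id(r0, c0 + 2L)
  C <- id(r0 + 2L, c0 + 2L); D <- id(r0 + 2L, c0)
  AB <- id(r0, c0 + 1L); BC <- id(r0 + 1L, c0 + 2L)
  CD <- id(r0 + 2L, c0 + 1L); DA <- id(r0 + 1L, c0)
  CE <- id(r0 + 1L, c0 + 1L)
  par <- (I + J) %% 2L == 0L
  E1 <- cbind(A, D, C, DA, CD, CE); E2 <- cbind(A, C, B, CE, BC, AB)
  E1b <- cbind(A, D, B, DA, CE, AB); E2b <- cbind(D, C, B, CD, BC, CE)
  E1[par, ] <- E1b[par, ]; E2[par, ] <- E2b[par, ]
  elems <- rbind(E1, E2)
  storage.mode(elems) <- "integer"

  ## region label per quad: block of layer I, demoted to fibrous outside the
  ## crescent's angular span
  blk_of_layer <- rep(seq_len(nb), vapply(blocks, `[[`, numeric(1), "n"))
  qlab <- vapply(blocks, `[[`, character(1), "label")[blk_of_layer[I]]
  qcap <- vapply(blocks, `[[`, logical(1), "cap")[blk_of_layer[I]]
  if (has_lip) {
    th_mid <- (theta[J] + theta[J + 1L]) / 2
    outside <- th_mid < theta_s
    demote <- outside & qlab %in% c("lp", "cag")
    qlab[demote] <- "ft"
    qcap[outside] <- FALSE
  }
  region <- c(qlab, qlab)
  cap <- c(qcap, qcap)

  ## ---- boundary edges (n1, mid, n2) --------------------------------------
  jj <- seq_len(n_th)
  edge_row <- function(i) cbind(id(rep(i, n_th), 2L * jj - 1L),
                                id(rep(i, n_th), 2L * jj),
                                id(rep(i, n_th), 2L * jj + 1L))
  ii <- seq_len(n_r)
  edge_col <- function(j) cbind(id(2L * ii - 1L, rep(j, n_r)),
                                id(2L * ii, rep(j, n_r)),
                                id(2L * ii + 1L, rep(j, n_r)))
  boundary <- list(
    lumen = edge_row(1L),
    outer_wall = edge_row(nr2),
    symmetry = rbind(edge_col(1L), edge_col(2L * n_th + 1L))
  )

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region, cap = cap,
    boundary = boundary, N = nrow(elems), level = level,
    lumen_center = c(cx, 0), lumen_radius = rl,
    half = TRUE, regions = regions
  ), class = "labeled_mesh")
  q <- mesh_quality(mesh)
  if (q$min_area <= 0)
    stop("meshing error: inverted element produced")
  mesh$quality <- q
  mesh
}

#' @exportS3Method base::print
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh (%s): %d nodes, %d quadratic triangles\n",
              x$level, nrow(x$nodes), x$N))
  print(table(x$region))
  cat(sprintf("  min corner angle %.1f deg, max skewness %.3f\n",
              x$quality$min_angle, x$quality$max_skewness))
  invisible(x)
}

#' Mesh quality metrics
#'
#' Corner-triangle angles, equilateral-deviation skewness and signed areas.
#'
#' @param mesh a \code{labeled_mesh}.
#' @return list with \code{min_angle} (degrees), \code{max_skewness},
#'   \code{min_area}, \code{areas} (per element, from corner nodes).
#' @export
mesh_quality <- function(mesh) {
  p1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$elems[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$elems[, 3], , drop = FALSE]
  cross <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  areas <- cross / 2
  len <- function(a, b) sqrt(rowSums((a - b)^2))
  a <- len(p2, p3); b <- len(p1, p3); cc <- len(p1, p2)
  ang <- function(opp, s1, s2)
    acos(pmin(1, pmax(-1, (s1^2 + s2^2 - opp^2) / (2 * s1 * s2))))
  A1 <- ang(a, b, cc); A2 <- ang(b, a, cc); A3 <- pi - A1 - A2
  th <- cbind(A1, A2, A3) * 180 / pi
  tmin <- apply(th, 1, min); tmax <- apply(th, 1, max)
  skew <- pmax((tmax - 60) / 120, (60 - tmin) / 60)
  list(min_angle = min(tmin), max_skewness = max(skew),
       min_area = min(areas), areas = areas)
}

#' Element areas summed by region
#'
#' Exact areas of the curved quadratic triangles, integrated
#' isoparametrically, aggregated by region label.
#'
#' @param mesh a \code{labeled_mesh}.
#' @return named numeric vector of areas (mm^2).
#' @export
mesh_region_areas <- function(mesh) {
  ar <- element_areas(mesh)
  tapply(ar, mesh$region, sum)
}

## exact area of curved T6 elements via the isoparametric Jacobian
element_areas <- function(mesh) {
  m <- mesh$N
  gp <- rbind(c(1 / 6, 1 / 6), c(2 / 3, 1 / 6), c(1 / 6, 2 / 3))
  dshape <- function(xi, eta) {
    L1 <- 1 - xi - eta
    cbind(c(1 - 4 * L1, 4 * xi - 1, 0, 4 * (L1 - xi), 4 * eta, -4 * eta),
          c(1 - 4 * L1, 0, 4 * eta - 1, -4 * xi, 4 * xi, 4 * (L1 - eta)))
  }
  total <- numeric(m)
  xs <- matrix(mesh$nodes[mesh$elems, 1], m, 6)
  ys <- matrix(mesh$nodes[mesh$elems, 2], m, 6)
  for (g in 1:3) {
    dN <- dshape(gp[g, 1], gp[g, 2])
    j11 <- xs %*% dN[, 1]; j12 <- xs %*% dN[, 2]
    j21 <- ys %*% dN[, 1]; j22 <- ys %*% dN[, 2]
    total <- total + (j11 * j22 - j12 * j21) / 6
  }
  as.vector(total)
}

#' Mirror a half mesh into a full cross-section mesh
#'
#' Reflects the half model across the symmetry line (the x-axis), merging
#' the nodes that lie on it, for full/half equivalence checks.
#'
#' @param mesh a half \code{labeled_mesh}.
#' @return a full \code{labeled_mesh} (no symmetry boundary).
#' @export
mirror_mesh <- function(mesh) {
  stopifnot(isTRUE(mesh$half))
  n <- nrow(mesh$nodes)
  on_axis <- mesh$nodes[, 2] == 0
  new_id <- integer(n)
  new_id[on_axis] <- which(on_axis)          # shared nodes keep identity
  extra <- which(!on_axis)
  new_id[extra] <- n + seq_along(extra)
  nodes <- rbind(mesh$nodes, cbind(mesh$nodes[extra, 1],
                                   -mesh$nodes[extra, 2]))
  ## mirrored elements: reverse orientation (corners 1,3,2; mids 6,5,4)
  me <- matrix(new_id[mesh$elems], ncol = 6)
  me <- me[, c(1, 3, 2, 6, 5, 4)]
  elems <- rbind(mesh$elems, me)
  storage.mode(elems) <- "integer"
  bmir <- function(ed) rbind(ed, matrix(new_id[ed], ncol = 3)[, c(3, 2, 1)])
  structure(list(
    nodes = nodes, elems = elems,
    region = c(mesh$region, mesh$region), cap = c(mesh$cap, mesh$cap),
    boundary = list(lumen = bmir(mesh$boundary$lumen),
                    outer_wall = bmir(mesh$boundary$outer_wall),
                    symmetry = NULL),
    N = nrow(elems), level = mesh$level,
    lumen_center = mesh$lumen_center, lumen_radius = mesh$lumen_radius,
    half = FALSE, regions = mesh$regions,
    quality = mesh$quality
  ), class = "labeled_mesh")
}

#' Grid-independence report
#'
#' Relative change of the critical stress and peak cap deformation between
#' successive refinement levels; the run passes when the fine-vs-medium
#' dissimilitude of both quantities is at most 2%.
#'
#' @param summaries list of \code{stress_summary} objects ordered from
#'   coarsest to finest (names are used as level labels if present).
#' @param tol pass tolerance on the last pair, as a fraction (default 0.02).
#' @return list with a per-pair data frame of percentage dissimilitudes and
#'   a logical \code{pass}.
#' @export
grid_independence <- function(summaries, tol = 0.02) {
  if (length(summaries) < 2)
    stop("insufficient-data: need summaries from at least two mesh levels")
  lev <- names(summaries)
  if (is.null(lev)) lev <- paste0("level", seq_along(summaries))
  sc <- vapply(summaries, function(s) s$sigma_cr, numeric(1))
  dm <- vapply(summaries, function(s) s$D_max, numeric(1))
  k <- seq_len(length(summaries) - 1)
  rel <- function(v) abs(v[k + 1] - v[k]) / abs(v[k]) * 100
  tab <- data.frame(from = lev[k], to = lev[k + 1],
                    sigma_cr_pct = rel(sc), D_max_pct = rel(dm))
  last <- nrow(tab)
  list(table = tab,
       pass = tab$sigma_cr_pct[last] <= tol * 100 &&
         tab$D_max_pct[last] <= tol * 100)
}
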