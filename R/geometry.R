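#' Parameterized plaque cross-section specification
#'
#' Describes one idealized half cross-section of a stenosed artery: a
#' circular wall (fixed internal/external diameter), an eccentric circular
#' lumen whose diameter follows from the degree of stenosis, fibrous plaque
#' filling the space between lumen and wall, and optionally a 140-degree
#' lipid crescent concentric with the lumen whose inner boundary lies a cap
#' thickness \code{d_fc} outside the lumen. A calcification agglomerate
#' crescent may occupy the lipid from depth \code{d_cg} (the calcification
#' gap, measured from the lipid's cap-side boundary) out to the lipid's
#' outer boundary, so its thickness is \code{lipid_thickness - d_cg}.
#'
#' Stenosis is diameter-based relative to the healthy internal diameter:
#' the lumen diameter is \code{L = (1 - stenosis) * internal_diameter}.
#' The lumen is shifted along the symmetry axis away from the plaque bulk,
#' so the crescents are bisected by the symmetry line and a half model is
#' valid. All lengths are in mm; \code{scale} multiplies every length.
#'
#' @param stenosis fractional diameter stenosis, strictly in (0, 1).
#' @param d_fc fibrous cap thickness (mm): radial distance from the lumen
#'   surface to the lipid's inner boundary.
#' @param d_cg calcification gap (mm). \code{NULL} (default) means a
#'   non-calcified plaque; \code{0} means the agglomerate touches the cap
#'   backing.
#' @param has_lipid logical; \code{FALSE} gives the homogeneous-wall model
#'   (model set A) with no lipid crescent.
#' @param internal_diameter,external_diameter arterial wall diameters (mm).
#' @param lumen_eccentricity offset of the lumen centre from the arterial
#'   centre along the symmetry axis (mm).
#' @param lipid_arc angular extent of the lipid crescent (degrees).
#' @param lipid_thickness radial thickness of the lipid crescent (mm).
#' @param scale dimensionless geometric scale applied to every length.
#' @return an object of class \code{plaque_geometry}.
#' @examples
#' spec <- plaque_geometry(stenosis = 0.70, d_fc = 0.05)
#' stenosis_to_lumen(spec)
#' @export
plaque_geometry <- function(stenosis, d_fc = 0.05, d_cg = NULL,
                            has_lipid = TRUE,
                            internal_diameter = 3.6, external_diameter = 4.0,
                            lumen_eccentricity = 0.5,
                            lipid_arc = 140, lipid_thickness = 0.35,
                            scale = 1) {
  if (!is.numeric(stenosis) || length(stenosis) != 1L ||
      stenosis <= 0 || stenosis >= 1)
    stop("invalid-parameter: stenosis must lie strictly in (0, 1)")
  if (scale <= 0)
    stop("invalid-parameter: scale must be positive")
  sp <- list(
    stenosis = stenosis,
    internal_diameter = internal_diameter * scale,
    external_diameter = external_diameter * scale,
    lumen_eccentricity = lumen_eccentricity * scale,
    lipid_arc = lipid_arc,
    lipid_thickness = lipid_thickness * scale,
    d_fc = d_fc * scale,
    d_cg = if (is.null(d_cg)) NULL else d_cg * scale,
    has_lipid = isTRUE(has_lipid),
    scale = scale
  )
  sp$L <- (1 - stenosis) * sp$internal_diameter
  sp$calcified <- sp$has_lipid && !is.null(sp$d_cg)
  sp$d_cag <- if (sp$calcified) sp$lipid_thickness - sp$d_cg else 0
  class(sp) <- "plaque_geometry"
  validate_plaque_geometry(sp)
  sp
}

#' Concentric annulus geometry (pressure-vessel benchmark)
#'
#' A plain half annulus with a concentric inner boundary, used to verify the
#' solver against the Lame thick-walled-cylinder closed form.
#'
#' @param inner_radius,outer_radius annulus radii (mm).
#' @return an object of class \code{c("annulus_geometry", "plaque_geometry")}.
#' @export
annulus_geometry <- function(inner_radius = 1.8, outer_radius = 2.0) {
  if (outer_radius <= inner_radius || inner_radius <= 0)
    stop("invalid-parameter: require 0 < inner_radius < outer_radius")
  sp <- list(
    internal_diameter = 2 * inner_radius,
    external_diameter = 2 * outer_radius,
    lumen_eccentricity = 0,
    has_lipid = FALSE, calcified = FALSE,
    L = 2 * inner_radius, stenosis = 0, scale = 1
  )
  class(sp) <- c("annulus_geometry", "plaque_geometry")
  sp
}

validate_plaque_geometry <- function(sp) {
  ri <- sp$internal_diameter / 2
  re <- sp$external_diameter / 2
  rl <- sp$L / 2
  if (!(re > ri && ri > rl && rl > 0))
    stop("infeasible-geometry: require external > internal > lumen diameter > 0")
  if (sp$lumen_eccentricity < 0)
    stop("invalid-parameter: lumen_eccentricity must be >= 0")
  if (sp$lumen_eccentricity + rl >= ri)
    stop("infeasible-geometry: lumen (radius + eccentricity) exceeds internal wall")
  if (sp$has_lipid) {
    if (sp$d_fc <= 0)
      stop("infeasible-geometry: cap thickness d_fc must be > 0")
    if (sp$lipid_thickness <= 0 || sp$lipid_arc <= 0 || sp$lipid_arc > 360)
      stop("invalid-parameter: lipid crescent arc/thickness out of range")
    if (sp$calcified) {
      if (sp$d_cg < 0)
        stop("invalid-parameter: calcification gap d_cg must be >= 0")
      if (sp$d_cg > sp$lipid_thickness)
        stop("infeasible-geometry: d_cg + d_cag exceeds lipid_thickness")
    }
    ## the lipid crescent must stay strictly inside the internal wall over
    ## its whole angular span (the closest approach is at the crescent tip)
    theta_s <- pi - (sp$lipid_arc / 2) * pi / 180
    b0 <- rl + sp$d_fc + sp$lipid_thickness
    Rmin <- internal_radius_at(theta_s, sp)
    if (b0 >= Rmin)
      stop(sprintf(paste0("infeasible-geometry: lipid outer boundary ",
                          "(%.3f mm) reaches the internal wall (%.3f mm at ",
                          "the crescent tip)"), b0, Rmin))
  }
  invisible(sp)
}

#' Lumen diameter from stenosis
#'
#' Diameter-based convention: \code{L = (1 - stenosis) * internal_diameter}.
#'
#' @param spec a \code{plaque_geometry} object.
#' @return lumen diameter L (mm).
#' @export
stenosis_to_lumen <- function(spec) {
  stopifnot(inherits(spec, "plaque_geometry"))
  spec$L
}

#' Cap thickness implied by stenosis with the lipid fixed in space
#'
#' In the constant-lipid model set the lipid crescent keeps its position
#' while the lumen grows or shrinks with stenosis, so the fibrous cap thins
#' as stenosis decreases. Anchoring the lipid's inner surface at a reference
#' (stenosis, cap thickness) pair gives the cap thickness at any other
#' stenosis.
#'
#' @param stenosis stenosis value(s) in (0, 1).
#' @param ref_stenosis,ref_d_fc anchor pair (defaults 0.70 and 0.05 mm).
#' @param internal_diameter healthy internal diameter (mm).
#' @return cap thickness (mm), vectorized over \code{stenosis}.
#' @export
cap_thickness_from_stenosis <- function(stenosis, ref_stenosis = 0.70,
                                        ref_d_fc = 0.05,
                                        internal_diameter = 3.6) {
  r_lip <- (1 - ref_stenosis) * internal_diameter / 2 + ref_d_fc
  d_fc <- r_lip - (1 - stenosis) * internal_diameter / 2
  if (any(d_fc <= 0))
    stop("infeasible-geometry: lumen overlaps the fixed lipid position")
  d_fc
}

## distance from the lumen centre to the internal-wall circle along the ray
## at angle theta (the half domain is star-shaped about the lumen centre)
internal_radius_at <- function(theta, sp) {
  ray_circle_distance(theta, sp$lumen_eccentricity, sp$internal_diameter / 2)
}
external_radius_at <- function(theta, sp) {
  ray_circle_distance(theta, sp$lumen_eccentricity, sp$external_diameter / 2)
}
ray_circle_distance <- function(theta, cx, R) {
  ## ray origin (cx, 0), direction (cos theta, sin theta), circle centre 0:
  ## solve |c + t u| = R for t > 0
  cu <- cx * cos(theta)
  -cu + sqrt(R^2 - cx^2 * sin(theta)^2)
}

#' Build the labeled planar region set of a half cross-section
#'
#' Constructs the closed planar regions of the half model bounded by the
#' symmetry line (the x-axis): non-diseased wall (\code{ndw}), fibrous
#' plaque including the cap (\code{ft}), lipid (\code{lp}) and calcification
#' agglomerate (\code{cag}). The crescents are annular sectors about the
#' lumen centre with flat radial end-cuts, so their areas equal the
#' closed-form annular-sector value exactly.
#'
#' @param spec a \code{plaque_geometry} object.
#' @return an object of class \code{plaque_regions} with the lumen-polar
#'   parametric description, closed-form region areas, and the region
#'   labels present.
#' @export
build_cross_section <- function(spec) {
  stopifnot(inherits(spec, "plaque_geometry"))
  ri <- spec$internal_diameter / 2
  re <- spec$external_diameter / 2
  rl <- spec$L / 2
  cx <- spec$lumen_eccentricity
  annulus <- inherits(spec, "annulus_geometry")

  blocks <- list()
  if (spec$has_lipid) {
    validate_plaque_geometry(spec)
    a0 <- rl + spec$d_fc
    gap <- if (spec$calcified) spec$d_cg else spec$lipid_thickness
    b0 <- a0 + spec$lipid_thickness
    blocks[["cap"]] <- list(label = "ft", cap = TRUE, r_in = rl, r_out = a0)
    if (gap > 0)
      blocks[["lipid"]] <- list(label = "lp", cap = FALSE, r_in = a0,
                                r_out = a0 + gap)
    if (spec$calcified && spec$d_cag > 0)
      blocks[["cag"]] <- list(label = "cag", cap = FALSE, r_in = a0 + gap,
                              r_out = b0)
    blocks[["fibrous"]] <- list(label = "ft", cap = FALSE, r_in = b0,
                                r_out = NA_real_)
  } else if (!annulus) {
    blocks[["fibrous"]] <- list(label = "ft", cap = FALSE, r_in = rl,
                                r_out = NA_real_)
  }
  blocks[["wall"]] <- list(label = "ndw", cap = FALSE, r_in = NA_real_,
                           r_out = NA_real_)

  theta_s <- if (spec$has_lipid) pi - (spec$lipid_arc / 2) * pi / 180 else NA

  ## closed-form areas (half model)
  arc <- if (spec$has_lipid) spec$lipid_arc * pi / 180 else 0
  sector_half_area <- function(a, b) arc * (b^2 - a^2) / 4
  area_wall <- pi * (re^2 - ri^2) / 2
  area_lip <- area_cag <- 0
  if (spec$has_lipid) {
    a0 <- rl + spec$d_fc
    gap <- if (spec$calcified) spec$d_cg else spec$lipid_thickness
    if (gap > 0) area_lip <- sector_half_area(a0, a0 + gap)
    if (spec$calcified && spec$d_cag > 0)
      area_cag <- sector_half_area(a0 + gap, a0 + spec$lipid_thickness)
  }
  area_fib <- if (annulus) 0 else
    pi * (ri^2 - rl^2) / 2 - area_lip - area_cag
  areas <- c(ndw = area_wall, ft = area_fib, lp = area_lip, cag = area_cag)
  areas <- areas[areas > 0 | names(areas) == "ndw"]

  structure(list(
    spec = spec, rl = rl, cx = cx, r_int = ri, r_ext = re,
    theta_s = theta_s, blocks = blocks, areas = areas,
    lumen_half_area = pi * rl^2 / 2,
    solid_half_area = pi * (re^2 - rl^2) / 2,
    annulus = annulus
  ), class = "plaque_regions")
}

#' @exportS3Method base::print
print.plaque_regions <- function(x, ...) {
  cat("plaque_regions: half cross-section\n")
  cat(sprintf("  lumen radius %.3f mm at (%.2f, 0); wall %.2f-%.2f mm\n",
              x$rl, x$cx, x$r_int, x$r_ext))
  cat("  regions:", paste(names(x$areas), collapse = ", "), "\n")
  cat("  areas (mm^2):",
      paste(sprintf("%s=%.4f", names(x$areas), x$areas), collapse = " "), "\n")
  invisible(x)
}

#' Region areas of a cross-section
#'
#' Closed-form planar areas (mm^2) of each labeled region of the half model.
#'
#' @param regions a \code{plaque_regions} object.
#' @return named numeric vector of areas by region label.
#' @export
region_areas <- function(regions) {
  stopifnot(inherits(regions, "plaque_regions"))
  regions$areas
}

#' Discretized boundary polygons per region
#'
#' Samples every region boundary as a closed, non-self-intersecting polygon,
#' for export and for polygon-based (shoelace) checks.
#'
#' @param regions a \code{plaque_regions} object.
#' @param n number of points per full arc span (resolution).
#' @return named list of two-column matrices (x, y), one closed loop each.
#' @export
region_polygons <- function(regions, n = 256) {
  sp <- regions$spec
  rl <- regions$rl; cx <- regions$cx
  ri <- regions$r_int; re <- regions$r_ext
  arc_pts <- function(th0, th1, r, ctr = 0) {
    th <- seq(th0, th1, length.out = max(8, ceiling(n * abs(th1 - th0) / pi)))
    cbind(ctr + r * cos(th), r * sin(th))
  }
  out <- list()
  out$ndw <- rbind(arc_pts(0, pi, re), arc_pts(pi, 0, ri))
  if (regions$annulus) return(out)
  if (!sp$has_lipid) {
    out$ft <- rbind(arc_pts(0, pi, rl, cx), arc_pts(pi, 0, ri))
    return(out)
  }
  ths <- regions$theta_s
  a0 <- rl + sp$d_fc
  gap <- if (sp$calcified) sp$d_cg else sp$lipid_thickness
  b0 <- a0 + sp$lipid_thickness
  ## fibrous: lumen arc, up the symmetry line, around the crescent, out to
  ## the internal wall and back
  out$ft <- rbind(
    arc_pts(0, pi, rl, cx),
    arc_pts(pi, ths, a0, cx),
    arc_pts(ths, pi, b0, cx),
    arc_pts(pi, 0, ri)
  )
  if (gap > 0)
    out$lp <- rbind(arc_pts(pi, ths, a0, cx), arc_pts(ths, pi, a0 + gap, cx))
  if (sp$calcified && sp$d_cag > 0)
    out$cag <- rbind(arc_pts(pi, ths, a0 + gap, cx), arc_pts(ths, pi, b0, cx))
  out
}

#' Shoelace polygon area
#'
#' @param poly two-column matrix of vertices (closure implied).
#' @return absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}
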