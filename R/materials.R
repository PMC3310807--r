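#' Orthotropic tissue properties
#'
#' Plane-stress material constants for one plaque constituent, in local
#' radial-circumferential axes. \code{nu_rtheta} is the minor Poisson ratio
#' paired with \code{E_r} (so the reciprocal ratio is
#' \code{nu_thetar = nu_rtheta * E_theta / E_r}). \code{nu_rz} is stored for
#' out-of-plane strain recovery but does not enter plane-stress equilibrium.
#'
#' @param tissue label, one of \code{ndw, ft, lp, Ca, cag}.
#' @param E_r,E_theta radial / circumferential Young moduli (kPa).
#' @param G_rtheta in-plane shear modulus (kPa).
#' @param nu_rtheta,nu_rz Poisson ratios (dimensionless).
#' @return an object of class \code{tissue_properties}.
#' @export
tissue_properties <- function(tissue, E_r, E_theta, G_rtheta,
                              nu_rtheta = 0.01, nu_rz = 0.27) {
  if (any(c(E_r, E_theta, G_rtheta) <= 0))
    stop(sprintf("material error (%s): all moduli must be positive", tissue))
  if (nu_rtheta < 0 || nu_rtheta >= 0.5)
    stop(sprintf("material error (%s): nu_rtheta outside [0, 0.5)", tissue))
  nu_tr <- nu_rtheta * E_theta / E_r
  if (1 - nu_rtheta * nu_tr <= 0)
    stop(sprintf("material error (%s): compliance not positive definite",
                 tissue))
  structure(list(tissue = tissue, E_r = E_r, E_theta = E_theta,
                 G_rtheta = G_rtheta, nu_rtheta = nu_rtheta, nu_rz = nu_rz),
            class = "tissue_properties")
}

#' @exportS3Method base::print
print.tissue_properties <- function(x, ...) {
  cat(sprintf("tissue '%s': E_r=%g E_theta=%g G=%g kPa, nu_rt=%g nu_rz=%g\n",
              x$tissue, x$E_r, x$E_theta, x$G_rtheta, x$nu_rtheta, x$nu_rz))
  invisible(x)
}

#' Reference material table for plaque constituents
#'
#' Orthotropic constants (kPa) for the non-diseased wall (\code{ndw}),
#' fibrous tissue (\code{ft}), lipid (\code{lp}) and micro-calcium
#' (\code{Ca}), plus the homogenized calcification agglomerate (\code{cag})
#' obtained from the rule of mixtures with fractions 5% fibrous / 20% lipid
#' / 75% calcium.
#'
#' @return named list of \code{tissue_properties}.
#' @export
tissue_table <- function() {
  base <- list(
    ndw = tissue_properties("ndw", 10, 100, 50),
    ft  = tissue_properties("ft", 50, 1000, 500),
    lp  = tissue_properties("lp", 1, 1, 1),
    Ca  = tissue_properties("Ca", 12600, 12600, 12600)
  )
  base$cag <- homogenize_agglomerate(base, mixture_fractions())
  base
}

#' Mixture fractions for the calcification agglomerate
#'
#' @param alpha,beta,gamma fibrous, lipid and calcium volume fractions; must
#'   each lie in [0, 1] and sum to one.
#' @return an object of class \code{mixture_fractions}.
#' @export
mixture_fractions <- function(alpha = 0.05, beta = 0.20, gamma = 0.75) {
  f <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(f < 0) || any(f > 1))
    stop("invalid-mixture: fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("invalid-mixture: fractions must sum to 1")
  structure(as.list(f), class = "mixture_fractions")
}

#' Homogenize the calcification agglomerate by the rule of mixtures
#'
#' Each modulus of the agglomerate is the linear combination
#' \code{alpha * ft + beta * lp + gamma * Ca} of the constituent moduli
#' (radial, circumferential, shear). Poisson ratios are carried over
#' unchanged, which is exact here because all constituents share them.
#'
#' @param base named list of \code{tissue_properties} containing at least
#'   \code{ft}, \code{lp} and \code{Ca}.
#' @param f a \code{mixture_fractions} object.
#' @return \code{tissue_properties} for tissue \code{cag}.
#' @export
homogenize_agglomerate <- function(base = tissue_table()[c("ft", "lp", "Ca")],
                                   f = mixture_fractions()) {
  stopifnot(inherits(f, "mixture_fractions"))
  need <- c("ft", "lp", "Ca")
  if (!all(need %in% names(base)))
    stop("invalid-mixture: base must contain ft, lp and Ca entries")
  mix <- function(field)
    f$alpha * base$ft[[field]] + f$beta * base$lp[[field]] +
      f$gamma * base$Ca[[field]]
  nus <- vapply(base[need], `[[`, numeric(1), "nu_rtheta")
  if (diff(range(nus)) > 1e-12)
    warning("constituent Poisson ratios differ; carrying over the ft value")
  tissue_properties("cag", mix("E_r"), mix("E_theta"), mix("G_rtheta"),
                    base$ft$nu_rtheta, base$ft$nu_rz)
}

#' Orthotropic plane-stress constitutive matrix
#'
#' Builds the local plane-stress compliance from \code{E_r}, \code{E_theta},
#' \code{nu_rtheta} (with the reciprocal ratio
#' \code{nu_thetar = nu_rtheta * E_theta / E_r}) and \code{G_rtheta},
#' inverts it to the local stiffness, and rotates into global axes by the
#' local material angle (radial direction at \code{theta_local}).
#'
#' @param t a \code{tissue_properties} object.
#' @param theta_local rotation angle of the local radial axis from the
#'   global x-axis (radians).
#' @param plane one of \code{"stress"} (default) or \code{"strain"}. The
#'   plane-strain variant augments the compliance with out-of-plane
#'   coupling, taking the axial modulus equal to \code{E_r} and axial
#'   ratios equal to \code{nu_rz}.
#' @return an object of class \code{constitutive_matrix}: list with the
#'   3x3 global stiffness \code{D}, the local stiffness \code{D_local} and
#'   the angle.
#' @export
plane_stress_matrix <- function(t, theta_local = 0,
                                plane = c("stress", "strain")) {
  stopifnot(inherits(t, "tissue_properties"))
  plane <- match.arg(plane)
  S <- local_compliance(t, plane)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(sprintf("material error (%s): compliance not positive definite",
                 t$tissue))
  Dl <- solve(S)
  Tm <- strain_transform(theta_local)
  D <- t(Tm) %*% Dl %*% Tm
  structure(list(D = D, D_local = Dl, angle = theta_local, tissue = t$tissue),
            class = "constitutive_matrix")
}

local_compliance <- function(t, plane = "stress") {
  S <- matrix(0, 3, 3)
  S[1, 1] <- 1 / t$E_r
  S[2, 2] <- 1 / t$E_theta
  S[1, 2] <- S[2, 1] <- -t$nu_rtheta / t$E_r   # = -nu_thetar / E_theta
  S[3, 3] <- 1 / t$G_rtheta
  if (plane == "strain") {
    ## condense the axial direction: E_z = E_r, nu_rz = nu_thetaz given
    Ez <- t$E_r
    srz <- -t$nu_rz / t$E_r
    stz <- -t$nu_rz / t$E_theta
    S3 <- c(srz, stz)
    S[1:2, 1:2] <- S[1:2, 1:2] - outer(S3, S3) / (1 / Ez)
  }
  S
}

## engineering-strain transformation global -> local for rotation phi
strain_transform <- function(phi) {
  c2 <- cos(phi)^2; s2 <- sin(phi)^2; cs <- cos(phi) * sin(phi)
  matrix(c(c2, s2, cs,
           s2, c2, -cs,
           -2 * cs, 2 * cs, c2 - s2), 3, 3, byrow = TRUE)
}

#' Default region material map
#'
#' Materials for the mesh regions \code{ndw}, \code{ft}, \code{lp} and
#' \code{cag}, from \code{\link{tissue_table}} with optional overrides of
#' the lipid and agglomerate stiffness used in the sensitivity sweeps. An
#' override sets the tissue quasi-isotropic
#' (\code{E_r = E_theta = G = value}) with the shared Poisson ratios.
#'
#' @param E_lp lipid Young modulus override (kPa), default 1.
#' @param E_cag agglomerate modulus override (kPa); \code{NULL} keeps the
#'   rule-of-mixtures values.
#' @param homogeneous logical; \code{TRUE} assigns fibrous tissue everywhere
#'   (homogeneous-wall model set A).
#' @return named list of \code{tissue_properties} keyed by region label.
#' @export
default_materials <- function(E_lp = 1, E_cag = NULL, homogeneous = FALSE) {
  tab <- tissue_table()
  mats <- list(ndw = tab$ndw, ft = tab$ft, lp = tab$lp, cag = tab$cag)
  if (!is.null(E_lp))
    mats$lp <- tissue_properties("lp", E_lp, E_lp, E_lp,
                                 tab$lp$nu_rtheta, tab$lp$nu_rz)
  if (!is.null(E_cag))
    mats$cag <- tissue_properties("cag", E_cag, E_cag, E_cag,
                                  tab$Ca$nu_rtheta, tab$Ca$nu_rz)
  if (homogeneous)
    mats$ndw <- mats$lp <- mats$cag <- mats$ft
  mats
}

#' Read / write the material table as CSV
#'
#' Columns: tissue, E_r, E_theta, G_rtheta, nu_rtheta, nu_rz (moduli in kPa).
#'
#' @param path file path.
#' @param mats named list of \code{tissue_properties}.
#' @return \code{read_material_table}: named list of
#'   \code{tissue_properties}; \code{write_material_table}: \code{path},
#'   invisibly.
#' @export
read_material_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "E_r", "E_theta", "G_rtheta", "nu_rtheta", "nu_rz")
  if (!all(need %in% names(df)))
    stop("material table must have columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    tissue_properties(df$tissue[i], df$E_r[i], df$E_theta[i], df$G_rtheta[i],
                      df$nu_rtheta[i], df$nu_rz[i]))
  setNames(out, df$tissue)
}

#' @rdname read_material_table
#' @export
write_material_table <- function(mats, path) {
  df <- do.call(rbind, lapply(mats, function(t)
    data.frame(tissue = t$tissue, E_r = t$E_r, E_theta = t$E_theta,
               G_rtheta = t$G_rtheta, nu_rtheta = t$nu_rtheta,
               nu_rz = t$nu_rz)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
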