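#' In-plane principal stresses from tensor components
#'
#' Closed-form eigenvalues of the symmetric 2x2 in-plane stress tensor.
#'
#' @param sxx,syy,sxy stress components (kPa), vectorized.
#' @return two-column matrix (s1 >= s2).
#' @export
principal_stresses <- function(sxx, syy, sxy) {
  m <- (sxx + syy) / 2
  r <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  cbind(s1 = m + r, s2 = m - r)
}

## per-element stress samples: either the raw Gauss-point values or the
## (unsmoothed) linear extrapolation of the Gauss values to the element
## corners, which recovers surface peaks the interior points under-read
element_stress_samples <- function(field, recovery = c("corner", "gauss")) {
  recovery <- match.arg(recovery)
  s <- field$stress_gp
  if (recovery == "gauss") {
    idx <- function(k) cbind(s[, k], s[, k + 3], s[, k + 6])
    xy <- field$gp_xy
    return(list(sxx = idx(1), syy = idx(2), sxy = idx(3),
                x = xy[, c(1, 3, 5)], y = xy[, c(2, 4, 6)]))
  }
  extrap <- function(k) {
    a <- (5 * s[, k] - s[, k + 3] - s[, k + 6]) / 3
    cbind(a, a + 2 * (s[, k + 3] - s[, k]), a + 2 * (s[, k + 6] - s[, k]))
  }
  mesh <- field$mesh
  list(sxx = extrap(1), syy = extrap(2), sxy = extrap(3),
       x = matrix(mesh$nodes[mesh$elems[, 1:3], 1], ncol = 3),
       y = matrix(mesh$nodes[mesh$elems[, 1:3], 2], ncol = 3))
}

#' Per-element maximum principal stress
#'
#' Largest eigenvalue of the in-plane stress tensor, sampled per element;
#' under plane stress the zero out-of-plane stress is included in the
#' eigen-set, so the element value is \code{max(0, max over samples)}. The
#' default recovery extrapolates the Gauss-point tensor linearly to the
#' element corners without cross-element averaging, so surface peaks (the
#' cap's outer fibre) are represented; \code{recovery = "gauss"} reports the
#' raw interior integration-point maximum instead.
#'
#' @param field a \code{plaque_solution}.
#' @param recovery \code{"corner"} (default) or \code{"gauss"}.
#' @return numeric vector, one value per element (kPa).
#' @export
principal_stress <- function(field, recovery = c("corner", "gauss")) {
  stopifnot(inherits(field, "plaque_solution"))
  sm <- element_stress_samples(field, recovery)
  s1 <- sapply(1:3, function(j)
    principal_stresses(sm$sxx[, j], sm$syy[, j], sm$sxy[, j])[, 1])
  if (is.null(dim(s1))) s1 <- matrix(s1, nrow = 1)
  pmax(0, apply(s1, 1, max))
}

#' Per-element peak circumferential stress
#'
#' Stress component along the circumferential direction about the arterial
#' centre; returns the per-element maximum over the recovery samples.
#'
#' @param field a \code{plaque_solution}.
#' @param recovery \code{"corner"} (default) or \code{"gauss"}.
#' @return numeric vector, one value per element (kPa).
#' @export
circumferential_stress <- function(field, recovery = c("corner", "gauss")) {
  stopifnot(inherits(field, "plaque_solution"))
  sm <- element_stress_samples(field, recovery)
  out <- matrix(0, nrow(sm$sxx), 3)
  for (j in 1:3) {
    ph <- atan2(sm$y[, j], sm$x[, j])
    sn <- sin(ph); cs <- cos(ph)
    out[, j] <- sn^2 * sm$sxx[, j] + cs^2 * sm$syy[, j] -
      2 * sn * cs * sm$sxy[, j]
  }
  apply(out, 1, max)
}

#' Summarize a solution into rupture-relevant scalars
#'
#' \code{sigma_cr} is the peak maximum principal stress restricted to the
#' fibrous-cap elements (the fibrous layer between lumen and lipid within
#' the crescent span); for models without a cap it falls back to the whole
#' fibrous region. \code{D_max} is the peak displacement magnitude over the
#' cap nodes. \code{sigma_over_P} normalizes the global peak circumferential
#' stress by the luminal pressure. Global peaks are reported alongside as
#' diagnostics.
#'
#' @param field a \code{plaque_solution}.
#' @param mesh,load default to those stored in \code{field}.
#' @param recovery stress recovery passed to \code{\link{principal_stress}}.
#' @return an object of class \code{stress_summary}.
#' @export
summarize_solution <- function(field, mesh = field$mesh, load = field$load,
                               recovery = c("corner", "gauss")) {
  stopifnot(inherits(field, "plaque_solution"))
  recovery <- match.arg(recovery)
  cap_el <- which(mesh$cap)
  if (!length(cap_el)) cap_el <- which(mesh$region == "ft")
  if (!length(cap_el))
    stop("summary error: mesh has no fibrous region")
  s1 <- principal_stress(field, recovery)
  sth <- circumferential_stress(field, recovery)
  umag <- sqrt(rowSums(field$u^2))

  i_cap <- cap_el[which.max(s1[cap_el])]
  sigma_cr <- s1[i_cap]
  cap_nodes <- unique(as.vector(mesh$elems[cap_el, ]))
  n_cap <- cap_nodes[which.max(umag[cap_nodes])]
  D_max <- umag[n_cap]
  i_glob <- which.max(s1)
  sm <- element_stress_samples(field, recovery)
  g_of <- function(e) {       # coordinates of the hottest sample point
    s1s <- principal_stresses(sm$sxx[e, ], sm$syy[e, ], sm$sxy[e, ])[, 1]
    j <- which.max(s1s)
    c(sm$x[e, j], sm$y[e, j])
  }
  structure(list(
    sigma_cr = sigma_cr,
    D_max = D_max,
    sigma_over_P = if (load$P > 0) max(sth) / load$P else NA_real_,
    sigma_max_global = s1[i_glob],
    D_max_global = max(umag),
    sigma_cr_element = i_cap, sigma_cr_xy = g_of(i_cap),
    sigma_max_element = i_glob, sigma_max_xy = g_of(i_glob),
    D_max_node = n_cap, D_max_xy = mesh$nodes[n_cap, ],
    P = load$P, level = mesh$level, N = mesh$N
  ), class = "stress_summary")
}

#' @exportS3Method base::print
print.stress_summary <- function(x, ...) {
  cat(sprintf(paste0("stress_summary: sigma_cr = %.4g kPa, D_max = %.4g mm",
                     " (P = %g kPa, N = %d)\n"),
              x$sigma_cr, x$D_max, x$P, x$N))
  cat(sprintf("  sigma/P = %.4g; global sigma_max = %.4g kPa, |u|max = %.4g mm\n",
              x$sigma_over_P, x$sigma_max_global, x$D_max_global))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.stress_summary <- function(x, ...) {
  data.frame(sigma_cr = x$sigma_cr, D_max = x$D_max,
             sigma_over_P = x$sigma_over_P,
             sigma_max_global = x$sigma_max_global,
             D_max_global = x$D_max_global, P = x$P, N = x$N)
}

#' Build, mesh, solve and summarize one plaque model
#'
#' Convenience pipeline: cross-section from the geometry spec, mesh at the
#' requested level, plane-stress solve, summary.
#'
#' @param spec a \code{plaque_geometry}.
#' @param materials region material map (default \code{default_materials()}).
#' @param load a \code{load_spec}.
#' @param level mesh level.
#' @return list with \code{mesh}, \code{solution} and \code{summary}.
#' @export
solve_model <- function(spec, materials = default_materials(),
                        load = load_spec(), level = "medium") {
  regions <- build_cross_section(spec)
  mesh <- generate_mesh(regions, level)
  sol <- solve_plane_stress(mesh, materials, load)
  list(mesh = mesh, solution = sol, summary = summarize_solution(sol))
}
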