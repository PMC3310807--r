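#' Export a mesh or solution as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid with quadratic-triangle
#' cells (VTK type 22), region labels as cell data, and — when given a
#' solution — nodal displacements as point vectors plus per-element maximum
#' principal and circumferential stress as cell data.
#'
#' @param x a \code{labeled_mesh} or \code{plaque_solution}.
#' @param path output file path (conventionally \code{.vtk}).
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(x, path) {
  if (inherits(x, "plaque_solution")) {
    mesh <- x$mesh; sol <- x
  } else if (inherits(x, "labeled_mesh")) {
    mesh <- x; sol <- NULL
  } else stop("write_vtk needs a labeled_mesh or plaque_solution")
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- mesh$N
  wl <- function(...) writeLines(..., con = con)
  wl("# vtk DataFile Version 3.0")
  wl("plaquefem unstructured grid")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0))
  wl(sprintf("CELLS %d %d", m, 7L * m))
  e0 <- mesh$elems - 1L
  wl(paste(6L, e0[, 1], e0[, 2], e0[, 3], e0[, 4], e0[, 5], e0[, 6]))
  wl(sprintf("CELL_TYPES %d", m))
  wl(paste(rep(22L, m)))
  reg_id <- as.integer(factor(mesh$region,
                              levels = c("ndw", "ft", "lp", "cag")))
  if (!is.null(sol)) {
    wl(sprintf("POINT_DATA %d", n))
    wl("VECTORS displacement double")
    wl(paste(sol$u[, 1], sol$u[, 2], 0))
  }
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  wl(paste(reg_id))
  if (!is.null(sol)) {
    wl("SCALARS max_principal_stress double 1")
    wl("LOOKUP_TABLE default")
    wl(paste(principal_stress(sol)))
    wl("SCALARS circumferential_stress double 1")
    wl("LOOKUP_TABLE default")
    wl(paste(circumferential_stress(sol)))
  }
  invisible(path)
}

#' Read / write a geometry spec as a flat YAML or JSON config
#'
#' @param spec a \code{plaque_geometry}.
#' @param path file path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{read_geometry_config}: a \code{plaque_geometry};
#'   \code{write_geometry_config}: \code{path}, invisibly.
#' @export
write_geometry_config <- function(spec, path) {
  stopifnot(inherits(spec, "plaque_geometry"))
  if (inherits(spec, "annulus_geometry"))
    stop("config round-trip is defined for plaque geometries")
  sc <- spec$scale
  lst <- list(stenosis = spec$stenosis,
              d_fc = spec$d_fc / sc,
              d_cg = if (spec$calcified) spec$d_cg / sc else NULL,
              has_lipid = spec$has_lipid,
              internal_diameter = spec$internal_diameter / sc,
              external_diameter = spec$external_diameter / sc,
              lumen_eccentricity = spec$lumen_eccentricity / sc,
              lipid_arc = spec$lipid_arc,
              lipid_thickness = spec$lipid_thickness / sc,
              scale = sc)
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(plaque_geometry, lst)
}

#' Export region polygons as GeoJSON
#'
#' One Polygon feature per region, labeled by tissue, for inspection in any
#' GIS-style viewer.
#'
#' @param regions a \code{plaque_regions}.
#' @param path output path.
#' @param n sampling resolution per arc.
#' @return \code{path}, invisibly.
#' @export
write_region_geojson <- function(regions, path, n = 256) {
  polys <- region_polygons(regions, n)
  feats <- lapply(names(polys), function(nm) {
    p <- polys[[nm]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(region = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i)
                                                     as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sweep summaries as CSV and JSON
#'
#' @param result a \code{sweep_result}.
#' @param csv_path,json_path output paths; either may be \code{NULL}.
#' @return invisibly, the paths written.
#' @export
write_sweep_result <- function(result, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(result)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(c(csv = csv_path, json = json_path))
}
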