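test_that("stenosis maps to lumen diameter under the diameter convention", {
  expect_equal(stenosis_to_lumen(plaque_geometry(0.70)), 1.08)
  expect_equal(stenosis_to_lumen(plaque_geometry(0.90, d_fc = 0.48)), 0.36)
  # healthy limit: lumen approaches the internal diameter
  healthy <- plaque_geometry(1e-9, has_lipid = FALSE, lumen_eccentricity = 0)
  expect_equal(stenosis_to_lumen(healthy), 3.6, tolerance = 1e-8)
  expect_error(plaque_geometry(0), "invalid-parameter")
  expect_error(plaque_geometry(1), "invalid-parameter")
  expect_error(plaque_geometry(-0.2), "invalid-parameter")
})

test_that("region areas are conserved and match closed forms", {
  for (spec in list(plaque_geometry(0.70, d_fc = 0.05),
                    plaque_geometry(0.70, d_fc = 0.05, d_cg = 0.1),
                    plaque_geometry(0.80, d_fc = 0.2, d_cg = 0.02),
                    plaque_geometry(0.70, has_lipid = FALSE))) {
    reg <- build_cross_section(spec)
    solid <- pi * (reg$r_ext^2 - reg$rl^2) / 2
    expect_equal(sum(region_areas(reg)), solid, tolerance = 1e-9)
  }
})

test_that("lipid crescent area equals the annular-sector closed form", {
  spec <- plaque_geometry(0.70, d_fc = 0.05)
  reg <- build_cross_section(spec)
  a <- reg$rl + spec$d_fc
  b <- a + spec$lipid_thickness
  sector <- (spec$lipid_arc * pi / 180) * (b^2 - a^2) / 4  # half model
  expect_equal(region_areas(reg)[["lp"]], sector, tolerance = 1e-12)
  # polygon (shoelace) agreement within 0.5%
  poly <- region_polygons(reg, n = 2048)$lp
  expect_lt(abs(polygon_area(poly) / sector - 1), 0.005)
})

test_that("calcification gap controls the region topology", {
  # non-calcified: no agglomerate region
  reg0 <- build_cross_section(plaque_geometry(0.70, d_fc = 0.05))
  expect_false("cag" %in% names(region_areas(reg0)))
  # zero gap: agglomerate inner boundary coincides with the cap backing
  regz <- build_cross_section(plaque_geometry(0.70, d_fc = 0.05, d_cg = 0))
  expect_false("lp" %in% names(region_areas(regz)))
  expect_equal(regz$blocks$cag$r_in, regz$rl + 0.05)
  # positive gap: lipid layer sits between cap and agglomerate
  regg <- build_cross_section(plaque_geometry(0.70, d_fc = 0.05, d_cg = 0.1))
  expect_equal(regg$blocks$cag$r_in - regg$blocks$lipid$r_in, 0.1)
})

test_that("infeasible geometries are rejected with the violated constraint", {
  expect_error(plaque_geometry(0.05, d_fc = 1.5), "infeasible-geometry")
  expect_error(plaque_geometry(0.70, d_fc = 0.05, d_cg = 0.5),
               "infeasible-geometry")
  expect_error(plaque_geometry(0.70, d_fc = -0.1), "infeasible-geometry")
  expect_error(plaque_geometry(0.1, lumen_eccentricity = 0.5),
               "infeasible-geometry")
})

test_that("cap thickness grows with stenosis when the lipid is fixed", {
  s <- c(0.70, 0.75, 0.80, 0.90)
  d <- cap_thickness_from_stenosis(s)
  expect_equal(d[1], 0.05)
  expect_true(all(diff(d) > 0))
  expect_error(cap_thickness_from_stenosis(0.3), "infeasible-geometry")
})

test_that("the half geometry mirrors into a valid full cross-section", {
  reg <- build_cross_section(plaque_geometry(0.70, d_fc = 0.05, d_cg = 0.1))
  half <- generate_mesh(reg, "coarse")
  full <- mirror_mesh(half)
  expect_equal(full$N, 2L * half$N)
  a_half <- mesh_region_areas(half)
  a_full <- mesh_region_areas(full)
  expect_equal(as.numeric(a_full), 2 * as.numeric(a_half), tolerance = 1e-9)
  expect_gt(mesh_quality(full)$min_area, 0)
})

test_that("geometry specs round-trip through YAML and JSON configs", {
  spec <- plaque_geometry(0.75, d_fc = 0.12, d_cg = 0.08, scale = 1)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_geometry_config(spec, path)
    back <- read_geometry_config(path)
    expect_equal(back$L, spec$L)
    expect_equal(back$d_fc, spec$d_fc)
    expect_equal(back$d_cg, spec$d_cg)
    unlink(path)
  }
})

test_that("the geometric scale multiplies every length", {
  s1 <- plaque_geometry(0.70, d_fc = 0.05)
  s2 <- plaque_geometry(0.70, d_fc = 0.05, scale = 2.775)
  expect_equal(s2$L, 2.775 * s1$L)
  expect_equal(s2$d_fc, 2.775 * s1$d_fc)
  a1 <- region_areas(build_cross_section(s1))
  a2 <- region_areas(build_cross_section(s2))
  expect_equal(as.numeric(a2), 2.775^2 * as.numeric(a1), tolerance = 1e-9)
})
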