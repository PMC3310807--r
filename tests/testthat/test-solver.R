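test_that("the pressurized annulus converges to the Lame closed form", {
  reg <- build_cross_section(annulus_geometry(1.8, 2.0))
  exact <- lame_sigma_theta()
  iso <- iso_tissue(100, 0.01)
  err <- sapply(c("coarse", "medium", "fine"), function(lev) {
    mesh <- generate_mesh(reg, lev)
    sol <- solve_plane_stress(mesh, list(ndw = iso), load_spec(14.6))
    abs(max(circumferential_stress(sol, "gauss")) / exact - 1)
  })
  expect_true(all(diff(err) < 0))            # monotone convergence
  expect_lt(err[["fine"]], 0.01)
})

test_that("the orthotropic annulus matches the axisymmetric closed form", {
  ft <- tissue_table()$ft
  reg <- build_cross_section(annulus_geometry(1.8, 2.0))
  mesh <- generate_mesh(reg, "fine")
  sol <- solve_plane_stress(mesh, list(ndw = ft), load_spec(14.6))
  ex <- ortho_annulus_exact(ft)
  expect_equal(max(circumferential_stress(sol, "gauss")),
               ex$sigma_theta(1.8), tolerance = 0.005)
  # displacements in the zero-net-translation frame equal the centred
  # axisymmetric solution
  expect_equal(max(sqrt(rowSums(sol$u^2))), ex$u(1.8), tolerance = 0.01)
})

test_that("zero load produces an identically zero field", {
  reg <- build_cross_section(fig9a_spec())
  mesh <- generate_mesh(reg, "coarse")
  sol <- solve_plane_stress(mesh, default_materials(E_lp = 1), load_spec(0))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(max(abs(sol$stress_gp)), 0)
  s <- summarize_solution(sol)
  expect_equal(s$sigma_cr, 0)
  expect_equal(s$D_max, 0)
})

test_that("the solution is exactly linear in the luminal pressure", {
  reg <- build_cross_section(fig9a_spec())
  mesh <- generate_mesh(reg, "coarse")
  mats <- default_materials(E_lp = 1)
  s1 <- solve_plane_stress(mesh, mats, load_spec(14.6))
  s2 <- solve_plane_stress(mesh, mats, load_spec(29.2))
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-9)
  expect_equal(s2$stress_gp, 2 * s1$stress_gp, tolerance = 1e-9)
})

test_that("equilibrium and constraint structure hold after a solve", {
  reg <- build_cross_section(fig9a_spec())
  mesh <- generate_mesh(reg, "medium")
  sol <- solve_plane_stress(mesh, default_materials(E_lp = 1), load_spec(14.6))
  expect_lt(sol$residual, 1e-10)
  expect_lt(max(abs(equilibrium_residual(sol))), 1e-8)
  # symmetry line: zero normal displacement
  on_axis <- mesh$nodes[, 2] == 0
  expect_equal(max(abs(sol$u[on_axis, 2])), 0)
})

test_that("the mirrored full model reproduces the half model", {
  reg <- build_cross_section(fig9a_spec())
  half <- generate_mesh(reg, "coarse")
  full <- mirror_mesh(half)
  mats <- default_materials(E_lp = 1)
  sh <- summarize_solution(solve_plane_stress(half, mats, load_spec(14.6)))
  sf <- summarize_solution(solve_plane_stress(full, mats, load_spec(14.6)))
  expect_equal(sf$sigma_cr, sh$sigma_cr, tolerance = 1e-6)
  expect_equal(sf$D_max, sh$D_max, tolerance = 1e-6)
})

test_that("principal stresses are objective under a rigid rotation", {
  reg <- build_cross_section(annulus_geometry(1.8, 2.0))
  full <- mirror_mesh(generate_mesh(reg, "coarse"))
  iso <- iso_tissue(100, 0.01)
  s0 <- solve_plane_stress(full, list(ndw = iso), load_spec(14.6))
  # rotate the whole model (nodes and thus loads/material axes) by pi
  rot <- full
  rot$nodes <- -full$nodes
  s1 <- solve_plane_stress(rot, list(ndw = iso), load_spec(14.6))
  p0 <- principal_stress(s0)
  p1 <- principal_stress(s1)
  expect_equal(p1, p0, tolerance = 1e-9)
})

test_that("solver errors are raised for incomplete inputs", {
  reg <- build_cross_section(fig9a_spec())
  mesh <- generate_mesh(reg, "coarse")
  expect_error(solve_plane_stress(mesh, list(ndw = iso_tissue()),
                                  load_spec(14.6)),
               "solver error: no material")
  expect_error(load_spec(-5), "invalid-parameter")
})

test_that("plane-strain kinematics stiffen the response as expected", {
  reg <- build_cross_section(annulus_geometry(1.8, 2.0))
  mesh <- generate_mesh(reg, "coarse")
  iso <- iso_tissue(100, 0.3)
  us <- solve_plane_stress(mesh, list(ndw = iso), load_spec(14.6), "stress")
  un <- solve_plane_stress(mesh, list(ndw = iso), load_spec(14.6), "strain")
  expect_lt(max(abs(un$u)), max(abs(us$u)))
})
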