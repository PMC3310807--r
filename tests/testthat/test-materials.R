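test_that("identity mixtures return the pure constituents", {
  tab <- tissue_table()
  pure_ca <- homogenize_agglomerate(tab, mixture_fractions(0, 0, 1))
  expect_equal(pure_ca$E_r, 12600)
  expect_equal(pure_ca$E_theta, 12600)
  expect_equal(pure_ca$G_rtheta, 12600)
  pure_ft <- homogenize_agglomerate(tab, mixture_fractions(1, 0, 0))
  expect_equal(pure_ft$E_r, tab$ft$E_r)
  expect_equal(pure_ft$E_theta, tab$ft$E_theta)
  expect_equal(pure_ft$G_rtheta, tab$ft$G_rtheta)
})

test_that("homogenization is linear in the fractions and bounded", {
  tab <- tissue_table()
  f1 <- mixture_fractions(0.3, 0.5, 0.2)
  f2 <- mixture_fractions(0.1, 0.2, 0.7)
  lam <- 0.37
  mix <- mixture_fractions(lam * f1$alpha + (1 - lam) * f2$alpha,
                           lam * f1$beta + (1 - lam) * f2$beta,
                           lam * f1$gamma + (1 - lam) * f2$gamma)
  h1 <- homogenize_agglomerate(tab, f1)
  h2 <- homogenize_agglomerate(tab, f2)
  hm <- homogenize_agglomerate(tab, mix)
  for (fld in c("E_r", "E_theta", "G_rtheta"))
    expect_equal(hm[[fld]], lam * h1[[fld]] + (1 - lam) * h2[[fld]],
                 tolerance = 1e-12)
  # bounds: homogenized moduli between min and max constituents
  cons <- sapply(tab[c("ft", "lp", "Ca")], `[[`, "E_r")
  expect_gte(h1$E_r, min(cons))
  expect_lte(h1$E_r, max(cons))
})

test_that("invalid mixtures are rejected", {
  expect_error(mixture_fractions(0.5, 0.5, 0.5), "invalid-mixture")
  expect_error(mixture_fractions(-0.1, 0.4, 0.7), "invalid-mixture")
  expect_error(homogenize_agglomerate(list(ft = tissue_table()$ft),
                                      mixture_fractions()),
               "invalid-mixture")
})

test_that("the isotropic limit reproduces the textbook plane-stress matrix", {
  E <- 200; nu <- 0.3
  t <- iso_tissue(E, nu)
  D <- plane_stress_matrix(t, 0)$D
  Dref <- E / (1 - nu^2) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  expect_equal(unname(D), Dref, tolerance = 1e-12)
  # rotation invariance for an isotropic material
  D45 <- plane_stress_matrix(t, pi / 4)$D
  expect_equal(unname(D45), Dref, tolerance = 1e-9)
})

test_that("rotation of the stiffness preserves its spectrum", {
  t <- tissue_table()$ft
  D0 <- plane_stress_matrix(t, 0)$D
  D2pi <- plane_stress_matrix(t, 2 * pi)$D
  expect_equal(D0, D2pi, tolerance = 1e-9)
  # in the Mandel (normalized shear) basis a rotation is orthogonal, so the
  # stiffness spectrum is invariant
  mandel <- function(D) {
    M <- diag(c(1, 1, sqrt(2)))
    M %*% D %*% M
  }
  ev0 <- eigen(mandel(D0), symmetric = TRUE, only.values = TRUE)$values
  for (phi in c(0.3, 1.1, 2.7)) {
    Dp <- plane_stress_matrix(t, phi)$D
    expect_equal(eigen(mandel(Dp), symmetric = TRUE,
                       only.values = TRUE)$values, ev0, tolerance = 1e-10)
    expect_true(all(eigen(Dp, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("Poisson reciprocity holds for every reference tissue", {
  for (t in tissue_table()) {
    S <- solve(plane_stress_matrix(t, 0)$D_local)
    # S12 = -nu_rtheta / E_r = -nu_thetar / E_theta
    expect_equal(S[1, 2], -t$nu_rtheta / t$E_r, tolerance = 1e-12)
    expect_equal(S[1, 2], S[2, 1], tolerance = 1e-14)
  }
})

test_that("inadmissible constants raise material errors naming the tissue", {
  expect_error(tissue_properties("bad", -1, 10, 5), "material error \\(bad\\)")
  expect_error(tissue_properties("bad", 10, 10, 5, 0.6), "material error")
  # minor ratio too large for the anisotropy contrast
  expect_error(tissue_properties("ft", 50, 1000, 500, 0.3), "material error")
})

test_that("the material table round-trips through CSV", {
  path <- tempfile(fileext = ".csv")
  write_material_table(tissue_table(), path)
  back <- read_material_table(path)
  expect_setequal(names(back), names(tissue_table()))
  expect_equal(back$cag$E_r, tissue_table()$cag$E_r)
  unlink(path)
})

test_that("material overrides set quasi-isotropic sweep tissues", {
  m <- default_materials(E_lp = 5, E_cag = 120)
  expect_equal(m$lp$E_r, 5)
  expect_equal(m$lp$G_rtheta, 5)
  expect_equal(m$cag$E_theta, 120)
  mh <- default_materials(homogeneous = TRUE)
  expect_equal(mh$ndw$E_theta, tissue_table()$ft$E_theta)
})
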