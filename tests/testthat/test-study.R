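test_that("a single-point sweep equals a direct solve", {
  cfg <- sweep_config("B", stenosis = 0.70, d_fc = 0.05, E_lp = 1,
                      level = "coarse")
  res <- run_sweep(cfg)
  expect_equal(nrow(res), 1L)
  direct <- solve_level(fig9a_spec(), "coarse")$summary
  expect_equal(res$sigma_cr, direct$sigma_cr)
  expect_equal(res$D_max, direct$D_max)
})

test_that("critical stress falls as the cap thickens", {
  cfg <- sweep_config("B", stenosis = 0.70, d_fc = c(0.05, 0.2, 0.48),
                      E_lp = 1, level = "coarse")
  res <- run_sweep(cfg)
  res <- res[order(res$d_fc), ]
  expect_true(all(diff(res$sigma_cr) < 0))
  expect_true(all(diff(res$D_max) < 0))
})

test_that("calcification never raises the cap stress at matched geometry", {
  non <- solve_level(fig9a_spec(), "coarse")$summary
  for (g in c(0.02, 0.175)) {
    calc <- solve_level(plaque_geometry(0.70, d_fc = 0.05, d_cg = g),
                        "coarse")$summary
    expect_lte(calc$sigma_cr, non$sigma_cr)
  }
})

test_that("cap stress rises with the calcification gap toward a plateau", {
  cfg <- sweep_config("C", stenosis = 0.70, d_fc = 0.05, E_lp = 1,
                      d_cg = c(0.02, 0.1, 0.2, 0.33), E_cag = 100,
                      level = "coarse")
  res <- run_sweep(cfg)
  res <- res[order(res$d_cg), ]
  expect_true(all(diff(res$sigma_cr) > 0))
  # stress and deformation positively correlated along the gap axis
  expect_gt(cor(res$sigma_cr, res$D_max), 0.9)
  # slope flattens: the increments shrink toward the plateau
  inc <- diff(res$sigma_cr) / diff(res$d_cg)
  expect_true(all(diff(inc) < 0))
})

test_that("threshold interpolation recovers hand-computed crossings", {
  fake <- data.frame(d_cg = c(0.02, 0.06), sigma_cr = c(282, 318),
                     D_max = c(0.29, 0.34), feasible = TRUE)
  thr <- find_threshold(fake, rupture_criteria(300), "d_cg")
  expect_true(thr$crossed)
  expect_equal(thr$value, 0.04)           # linear interpolation by hand
  expect_equal(thr$D_max_at_crossing, 0.315)
  # threshold exactly at a grid point
  fake2 <- data.frame(d_cg = c(0.02, 0.06), sigma_cr = c(300, 318),
                      D_max = c(0.29, 0.34), feasible = TRUE)
  thr2 <- find_threshold(fake2, rupture_criteria(300), "d_cg")
  expect_equal(thr2$value, 0.02)
  # never crossed: flagged, not an error
  fake3 <- data.frame(d_cg = c(0.02, 0.06), sigma_cr = c(120, 140),
                      D_max = c(0.1, 0.2), feasible = TRUE)
  thr3 <- find_threshold(fake3, rupture_criteria(300), "d_cg")
  expect_false(thr3$crossed)
  expect_equal(thr3$flag, "stable over range")
})

test_that("vulnerability verdicts follow the rupture criteria", {
  mk <- function(sig) structure(list(sigma_cr = sig), class = "stress_summary")
  spec <- fig9a_spec()
  expect_equal(classify_plaque(mk(331), spec)$verdict, "rupture-risk")
  expect_equal(classify_plaque(mk(28.7), spec)$verdict, "stable")
  expect_true(classify_plaque(mk(28.7), spec)$thin_cap)  # 0.05 < 0.065
  thick <- fig9b_spec()
  expect_false(classify_plaque(mk(28.7), thick)$thin_cap)
})

test_that("the pressure waveform respects its stated extremes", {
  w <- pressure_waveform(peak = 107, diastolic = 70)
  t <- seq(0, w$period, length.out = 2000)
  p <- waveform_pressure(w, t)
  expect_equal(max(p), 107, tolerance = 1e-6)
  expect_gte(min(p), 0)
  expect_error(pressure_waveform(peak = 60, diastolic = 70), "waveform error")
})

test_that("the quasi-static envelope scales the reference summary", {
  ref <- structure(list(sigma_cr = 300, D_max = 0.3, P = 14.6),
                   class = "stress_summary")
  # constant waveform at the reference pressure: flat series
  env <- pulsatile_envelope(function(t) rep(14.6, length(t)), ref)
  expect_equal(unique(env$sigma_cr), 300)
  # zero waveform: zero series
  env0 <- pulsatile_envelope(function(t) rep(0, length(t)), ref)
  expect_equal(unique(env0$sigma_cr), 0)
  # 107 mmHg peak against the 14.6 kPa reference: ratio 0.977
  w <- pressure_waveform(peak = 107)
  env1 <- pulsatile_envelope(w, ref)
  expect_equal(max(env1$sigma_cr) / 300, mmhg_to_kpa(107) / 14.6,
               tolerance = 1e-6)
  expect_equal(max(env1$sigma_cr) / 300, 0.977, tolerance = 1e-3)
  expect_error(pulsatile_envelope(function(t) rep(-1, length(t)), ref),
               "waveform error")
})

test_that("sweeps are deterministic and skip infeasible points gracefully", {
  cfg <- sweep_config("C", stenosis = 0.70, d_fc = 0.05, E_lp = 1,
                      d_cg = c(0.02, 0.36), E_cag = 100, level = "coarse")
  expect_warning(res <- run_sweep(cfg), "infeasible")
  expect_equal(sum(res$feasible), 1L)
  cfg2 <- sweep_config("B", stenosis = 0.70, d_fc = 0.05, level = "coarse")
  expect_identical(run_sweep(cfg2)$sigma_cr, run_sweep(cfg2)$sigma_cr)
})

test_that("the lipid-pool model concentrates more stress than a homogeneous wall", {
  tab <- validate_homogeneous_vs_lipid(c(0.70, 0.80), level = "coarse")
  expect_true(all(tab$sigma_over_P_lipid > tab$sigma_over_P_homogeneous))
  # with the lipid fixed, higher stenosis means a thicker cap and less stress
  expect_lt(tab$sigma_over_P_lipid[2], tab$sigma_over_P_lipid[1])
})
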