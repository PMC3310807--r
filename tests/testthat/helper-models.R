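# shared fixtures: geometry specs and small cached solves used across files

fig9a_spec <- function() plaque_geometry(0.70, d_fc = 0.05)
fig9b_spec <- function() plaque_geometry(0.90, d_fc = 0.48)

lame_sigma_theta <- function(a = 1.8, b = 2.0, P = 14.6)
  P * (a^2 + b^2) / (b^2 - a^2)

# orthotropic pressurized annulus closed form (u = A r^k + B r^-k)
ortho_annulus_exact <- function(t, a = 1.8, b = 2.0, P = 14.6) {
  nutr <- t$nu_rtheta * t$E_theta / t$E_r
  den <- 1 - t$nu_rtheta * nutr
  Drr <- t$E_r / den
  Dtt <- t$E_theta / den
  Drt <- nutr * t$E_r / den
  k <- sqrt(Dtt / Drr)
  c1 <- Drr * k + Drt
  c2 <- -Drr * k + Drt
  M <- rbind(c(c1 * a^(k - 1), c2 * a^(-k - 1)),
             c(c1 * b^(k - 1), c2 * b^(-k - 1)))
  AB <- solve(M, c(-P, 0))
  list(
    sigma_theta = function(r)
      AB[1] * (Drt * k + Dtt) * r^(k - 1) +
      AB[2] * (-Drt * k + Dtt) * r^(-k - 1),
    u = function(r) AB[1] * r^k + AB[2] * r^(-k)
  )
}

iso_tissue <- function(E = 100, nu = 0.3)
  tissue_properties("ndw", E, E, E / (2 * (1 + nu)), nu)

solve_level <- function(spec, level, mats = default_materials(E_lp = 1),
                        P = 14.6) {
  solve_model(spec, mats, load_spec(P), level)
}
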