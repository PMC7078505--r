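# Microvascular transport rates against independent hand unit-conversion
# oracles (explicit SI arithmetic, not the package's own conversion path).

test_that("sedimentation velocity matches the SI hand oracle and scaling laws", {
  np <- nanoparticle(radius_nm = 50, density_g_cm3 = 2)
  env <- blood_env(mu_cP = 4)
  # oracle: (2/9) * ((2000 - 1000) kg/m^3 / 4e-3 Pa s) * 9.8 * (50e-9)^2
  v_oracle <- (2 / 9) * (1000 / 4e-3) * 9.8 * (50e-9)^2
  expect_equal(sedimentation_velocity(np, env), v_oracle, tolerance = 1e-10)
  expect_equal(v_oracle, 1.36e-9, tolerance = 5e-3)

  # neutral buoyancy
  np0 <- nanoparticle(radius_nm = 50, density_g_cm3 = 1)
  expect_equal(sedimentation_velocity(np0, env), 0)

  # r^2 scaling
  np2 <- nanoparticle(radius_nm = 100, density_g_cm3 = 2)
  expect_equal(sedimentation_velocity(np2, env) /
                 sedimentation_velocity(np, env), 4, tolerance = 1e-12)
})

test_that("Brownian diffusivity follows Stokes-Einstein", {
  env <- blood_env(mu_cP = 4)
  np <- nanoparticle(radius_nm = 50)
  D_oracle <- 1.38e-23 * 310 / (6 * pi * 4e-3 * 50e-9)
  expect_equal(brownian_diffusivity(np, env), D_oracle, tolerance = 1e-10)
  expect_equal(D_oracle, 1.135e-12, tolerance = 1e-3)

  # the tumor-viscosity value feeding the 90 nm permeability
  np45 <- nanoparticle(radius_nm = 45)
  D45 <- brownian_diffusivity(np45, blood_env(mu_cP = 7.42))
  expect_equal(D45, 1.38e-23 * 310 / (6 * pi * 7.42e-3 * 45e-9),
               tolerance = 1e-10)
  expect_equal(D45, 6.80e-13, tolerance = 2e-3)

  # 1/r scaling
  expect_equal(brownian_diffusivity(nanoparticle(radius_nm = 100), env),
               brownian_diffusivity(np, env) / 2, tolerance = 1e-12)
})

test_that("shear-induced and effective diffusivity combine correctly", {
  cap <- capillary()
  env <- blood_env(H = 0.45)
  D_S_oracle <- 0.3 * (3.6e-6)^2 * 116 * 0.45^2
  expect_equal(shear_induced_diffusivity(env, cap), D_S_oracle,
               tolerance = 1e-10)
  expect_equal(D_S_oracle, 9.13e-11, tolerance = 1e-3)

  # no erythrocytes -> no shear enhancement
  expect_equal(shear_induced_diffusivity(blood_env(H = 0), cap), 0)

  # quadratic in H
  expect_equal(shear_induced_diffusivity(blood_env(H = 0.4), cap) /
                 shear_induced_diffusivity(blood_env(H = 0.2), cap), 4,
               tolerance = 1e-12)

  np <- nanoparticle(radius_nm = 50)
  D <- effective_diffusivity(np, env, cap)
  expect_equal(D, brownian_diffusivity(np, env) + D_S_oracle,
               tolerance = 1e-12)
  expect_gte(D, max(brownian_diffusivity(np, env), D_S_oracle))
  expect_equal(effective_diffusivity(np, blood_env(H = 0), cap),
               brownian_diffusivity(np, blood_env(H = 0)))
})

test_that("wall deposition rate chains sedimentation, diffusion and Peclet", {
  np <- nanoparticle(radius_nm = 50, density_g_cm3 = 2)
  env <- blood_env()
  cap <- capillary()
  # chained SI oracle
  v <- (2 / 9) * (1000 / 4e-3) * 9.8 * (50e-9)^2
  D <- 1.38e-23 * 310 / (6 * pi * 4e-3 * 50e-9) +
    0.3 * (3.6e-6)^2 * 116 * 0.45^2
  k_on_oracle <- v * D * 1e-3 / (553e-6 * (5e-6)^3)
  expect_equal(wall_deposition_rate(np, env, cap), k_on_oracle,
               tolerance = 1e-10)
  expect_equal(k_on_oracle, 1.82e-3, tolerance = 2e-3)

  # neutral density -> zero deposition; buoyant -> clamped to zero
  expect_equal(wall_deposition_rate(nanoparticle(radius_nm = 50,
                                                 density_g_cm3 = 1),
                                    env, cap), 0)
  expect_equal(wall_deposition_rate(nanoparticle(radius_nm = 50,
                                                 density_g_cm3 = 0.5),
                                    env, cap), 0)

  # 1/u scaling at fixed D
  cap2 <- capillary(u_um_s = 2 * 553)
  expect_equal(wall_deposition_rate(np, env, cap2),
               wall_deposition_rate(np, env, cap) / 2, tolerance = 1e-12)
})

test_that("dislodging rate is glycocalyx-limited Brownian escape", {
  np <- nanoparticle(radius_nm = 50)
  env <- blood_env(mu_cP = 4)
  cap <- capillary(l_g_nm = 100)
  k_off_oracle <- (1.38e-23 * 310 / (6 * pi * 4e-3 * 50e-9)) / (100e-9)^2
  expect_equal(wall_dislodging_rate(np, env, cap), k_off_oracle,
               tolerance = 1e-10)
  expect_equal(k_off_oracle, 113.5, tolerance = 1e-3)

  # l_g^2 scaling
  expect_equal(wall_dislodging_rate(np, env, capillary(l_g_nm = 400)),
               wall_dislodging_rate(np, env, cap) / 16, tolerance = 1e-12)
})

test_that("phagocytosis rate is the inverse wrapping time, with a ceiling", {
  np <- nanoparticle(radius_nm = 50)
  k_mac_oracle <- 1e-17 / (4 * pi * (50e-9)^2 * 6e-5)
  expect_equal(phagocytosis_rate(np), k_mac_oracle, tolerance = 1e-10)
  expect_equal(k_mac_oracle, 5.3, tolerance = 2e-3)

  # 1/r^2 scaling
  expect_equal(phagocytosis_rate(nanoparticle(radius_nm = 100)),
               phagocytosis_rate(np) / 4, tolerance = 1e-12)

  # divergence at small r is clamped
  tiny <- nanoparticle(radius_nm = 0.1)
  expect_equal(phagocytosis_rate(tiny), phagocyte()$k_mac_cap)
  expect_lt(phagocytosis_rate(tiny, phagocyte(k_mac_cap_s = 1e6)), 1e6 + 1)
})

test_that("hindrance factors obey limits, monotonicity and the Renkin value", {
  h0 <- hindrance_factors(0)
  expect_equal(h0$F, 1)
  expect_equal(h0$G, 1)
  h1 <- hindrance_factors(c(1, 1.5))
  expect_equal(h1$F, c(0, 0))
  expect_equal(h1$G, c(0, 0))

  # hand evaluation of the Renkin polynomial at alpha = 0.1
  a <- 0.1
  F_oracle <- (1 - a)^2 * (1 - 2.104 * a + 2.09 * a^3 - 0.95 * a^5)
  expect_equal(hindrance_factors(a)$F, F_oracle, tolerance = 1e-12)
  expect_equal(F_oracle, 0.641, tolerance = 1e-3)

  grid <- seq(0, 1, by = 0.001)
  h <- hindrance_factors(grid)
  expect_true(all(h$F >= 0 & h$F <= 1))
  expect_true(all(h$G >= 0 & h$G <= 1))
  expect_true(all(diff(h$F[grid < 1]) <= 1e-12))
  expect_true(all(diff(h$G[grid < 1]) <= 1e-12))

  expect_error(hindrance_factors(-0.1), "non-negative")
})

test_that("reflection coefficient: limits, hand value, monotone in alpha", {
  # free filtration limit (point solute)
  expect_equal(sigma_from_alpha(0), 0)

  # particle exceeds pore -> complete exclusion
  np10 <- nanoparticle(diameter_nm = 10)
  expect_identical(reflection_coefficient(np10, pore_geometry(2.5)), 1)

  # hand evaluation with hindrance forced to unity
  unit_h <- function(a) list(F = rep(1, length(a)), G = rep(1, length(a)))
  a <- 0.5
  sig_oracle <- 1 - ((1 - (1 - (1 - a)^2)^2) * 1 +
                       (16 / 9) * a^2 * (1 - a)^2 * 1)
  expect_equal(sigma_from_alpha(0.5, unit_h), sig_oracle, tolerance = 1e-12)
  expect_equal(sig_oracle, 0.451, tolerance = 2e-3)

  # sigma in [0,1] and non-decreasing over a dense grid and random draws
  grid <- seq(0, 1.2, by = 0.001)
  s <- sigma_from_alpha(grid)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s) >= -1e-12))

  set.seed(11)
  draws <- runif(2000, 0, 3)
  sd_ <- sigma_from_alpha(draws)
  expect_true(all(sd_ >= 0 & sd_ <= 1))
})

test_that("tumor permeability matches hand oracle and decreases with size", {
  # independent SI evaluation for the 90 nm particle
  D_B <- 1.38e-23 * 310 / (6 * pi * 7.42e-3 * 45e-9)
  a <- 45 / 850
  F_ <- (1 - a)^2 * (1 - 2.104 * a + 2.09 * a^3 - 0.95 * a^5)
  P_oracle_mm_s <- 0.001 * (1 - a) * F_ * D_B / 5e-6 * 1e3
  P90 <- vascular_permeability(nanoparticle(diameter_nm = 90), tumor_pore(),
                               tumor_blood())
  expect_equal(P90, P_oracle_mm_s, tolerance = 1e-10)

  # P strictly decreasing in r over alpha in (0, 1)
  radii <- seq(5, 800, length.out = 40)
  Ps <- vapply(radii, function(r)
    vascular_permeability(nanoparticle(radius_nm = r), tumor_pore(),
                          tumor_blood()), 0)
  expect_true(all(diff(Ps) < 0))

  # no pores -> no permeability; particle larger than pore -> zero
  expect_equal(vascular_permeability(nanoparticle(diameter_nm = 90),
                                     pore_geometry(850, 5, phi = 0),
                                     tumor_blood()), 0)
  expect_equal(vascular_permeability(nanoparticle(radius_nm = 900),
                                     tumor_pore(), tumor_blood()), 0)
  expect_error(vascular_permeability(nanoparticle(diameter_nm = 90),
                                     pore_geometry(850), tumor_blood()),
               "phi")
})

test_that("invalid physical inputs are rejected", {
  expect_error(nanoparticle(radius_nm = -1), "positive")
  expect_error(nanoparticle(diameter_nm = 10, radius_nm = 5), "exactly one")
  expect_error(blood_env(mu_cP = 0), "positive")
  expect_error(blood_env(H = 1), "0, 1")
  expect_error(capillary(u_um_s = -5), "positive")
  expect_error(wall_deposition_rate(nanoparticle(radius_nm = 50),
                                    blood_env(),
                                    structure(list(u = 0, R = 5, l = 1000,
                                                   l_g = 100,
                                                   gamma_dot = 116),
                                              class = "capillary")),
               "Peclet")
})
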