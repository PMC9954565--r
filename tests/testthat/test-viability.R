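test_that("without uptake, nutrients relax to their supply levels", {
  dom <- static_culture_domain(dr_um = 50, dz_um = 50)
  sp <- list(
    list(species = species_params("oxygen", 3e-9, 2e-9,
                                  uptake = mm_kinetics(0, 5e-3)),
         top = "dirichlet", C_top = 0.2, C_init = 0.1),
    glucose_species(Vmax = 0))
  v <- simulate_static_culture(dom, sp, t_end = 12 * 3600, dt = 120)
  # oxygen climbs to saturation everywhere
  o2 <- v$species$oxygen
  expect_equal(o2$min_tissue[length(o2$min_tissue)], 0.2, tolerance = 1e-3)
  # glucose reservoir untouched
  glc <- v$species$glucose
  expect_equal(glc$min_tissue, rep(25, length(glc$min_tissue)),
               tolerance = 1e-9)
})

test_that("defaults keep a 500 um tissue above both Km for 24 h culture", {
  dom <- static_culture_domain()
  v <- simulate_static_culture(dom, t_end = 86400, dt = 120)
  expect_true(survives(v, "oxygen"))
  expect_true(survives(v, "glucose"))
  expect_gte(min_core_concentration(v, "glucose", 86400),
             v$species$glucose$Km)
  expect_gte(min_core_concentration(v, "oxygen", 86400),
             v$species$oxygen$Km)
  # t = 0 returns the initial concentration
  expect_equal(min_core_concentration(v, "oxygen", 0), 0.2)
  expect_error(min_core_concentration(v, "lactate", 0), "unknown species")
  # glucose minimum is non-increasing (finite reservoir)
  glc <- v$species$glucose$min_tissue
  expect_true(all(diff(glc) <= 1e-9))
})

test_that("zeroth-order limit reproduces the steady sphere centre deficit", {
  # C >> Km: deficit = Vmax R^2 / (6 D_tissue)
  dr <- 5
  dom <- sphere_in_bath_domain(250, 100, dr, dr)
  Vmax <- 2e-3; Dt <- 1.2e-9
  sp <- list(species = species_params("nut", 1e-6, Dt,
                                      uptake = mm_kinetics(Vmax, 1e-6)),
             top = "dirichlet", C_top = 10, C_init = 10)
  v <- simulate_static_culture(dom, list(sp), t_end = 400, dt = 2)
  deficit <- 10 - min(v$species$nut$min_tissue)
  R_eff <- (250 + dr / 2) * 1e-6
  expect_equal(deficit, Vmax * R_eff^2 / (6 * Dt),
               tolerance = 0.03)
})

test_that("first-order limit matches the Thiele-modulus effectiveness factor", {
  # C << Km: rate k1 C with k1 = Vmax / Km; eta = 3 (phi coth phi - 1) / phi^2
  dr <- 5
  dom <- sphere_in_bath_domain(250, 100, dr, dr)
  Dt <- 1.2e-9; Km <- 100; C0 <- 0.1
  R_eff <- (250 + dr / 2) * 1e-6
  phi <- 2
  k1 <- phi^2 * Dt / R_eff^2
  sp <- list(species = species_params("nut", 1e-6, Dt,
                                      uptake = mm_kinetics(k1 * Km, Km)),
             top = "dirichlet", C_top = C0, C_init = C0)
  v <- simulate_static_culture(dom, list(sp), t_end = 300, dt = 1)
  rate <- v$species$nut$mass$final_uptake_rate
  V_sph <- 4 / 3 * pi * R_eff^3
  eta_num <- rate / (k1 * C0 * V_sph)
  eta_an <- 3 * (phi / tanh(phi) - 1) / phi^2
  expect_equal(eta_num, eta_an, tolerance = 0.05)
})

test_that("glucose mass balance closes to better than 1%", {
  dom <- static_culture_domain(dr_um = 50, dz_um = 50)
  v <- simulate_static_culture(dom, t_end = 12 * 3600, dt = 120)
  m <- v$species$glucose$mass
  # initial reservoir - remaining - consumed
  expect_lt(abs(m$initial - m$final - m$consumed) / m$initial, 0.01)
  # oxygen steady state: boundary influx balances consumption
  mo <- v$species$oxygen$mass
  last_influx_rate <- NULL  # steady balance read from the ledger closure
  expect_lt(mo$closure, 0.02)
})

test_that("doubling Vmax weakly decreases the minimum concentration", {
  dom <- static_culture_domain(dr_um = 50, dz_um = 50)
  v1 <- simulate_static_culture(dom, list(oxygen_species(Vmax = 1e-3)),
                                t_end = 4 * 3600, dt = 120)
  v2 <- simulate_static_culture(dom, list(oxygen_species(Vmax = 2e-3)),
                                t_end = 4 * 3600, dt = 120)
  expect_lte(min(v2$species$oxygen$min_tissue),
             min(v1$species$oxygen$min_tissue))
})

test_that("survival is monotone in tissue size", {
  d500 <- static_culture_domain(tissue_model("sphere", 500),
                                dr_um = 50, dz_um = 50)
  d250 <- static_culture_domain(tissue_model("sphere", 250),
                                dr_um = 50, dz_um = 50)
  v500 <- simulate_static_culture(d500, t_end = 6 * 3600, dt = 120)
  v250 <- simulate_static_culture(d250, t_end = 6 * 3600, dt = 120)
  for (spn in c("oxygen", "glucose")) {
    expect_gte(min(v250$species[[spn]]$min_tissue),
               min(v500$species[[spn]]$min_tissue))
  }
})

test_that("medium refresh check passes at defaults and fails on a starved reservoir", {
  dom <- static_culture_domain(dr_um = 50, dz_um = 50)
  ok <- medium_refresh_check(dom, interval_s = 6 * 3600, dt = 120)
  expect_true(all(ok))
  expect_true(all(medium_refresh_check(dom, interval_s = 0)))
  # 1% of the glucose reservoir starts below Km already and collapses
  poor <- list(glucose_species(C_glc0 = 0.25))
  bad <- medium_refresh_check(dom, poor, interval_s = 24 * 3600, dt = 300)
  expect_false(bad[["glucose"]])
})
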