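test_that("null forcing keeps the well empty", {
  dom <- well_domain(tissue_model("sphere", 500), dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), C_mouth = 0,
                               t_end = 100, dt = 5)
  expect_true(all(abs(h$frames[!is.na(h$frames)]) < 1e-14))
  expect_equal(unname(time_to_steady_state(h, threshold = 0)), 0)
})

test_that("a fully mixed tissue-free well equilibrates within one step", {
  dom <- well_domain(tissue = NULL, mixed_depth_um = 900,
                     dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), 1, t_end = 20, dt = 2)
  last <- h$frames[, , dim(h$frames)[3]]
  expect_true(all(abs(last[!is.na(last)] - 1) < 0.01))
})

test_that("the well acts as a 1D slab and matches the Fourier series t95", {
  # radially uniform boundary conditions + uniform D => slab of L = 0.9 mm
  dom <- well_domain(tissue = NULL, dr_um = 25, dz_um = 15)
  h <- simulate_well_transport(dom, reagent_species(), 1,
                               t_end = 1500, dt = 2,
                               save_times = seq(0, 1500, by = 10))
  bottom <- vapply(seq_along(h$save_times),
                   function(k) h$frames[1, 1, k], numeric(1))
  t95 <- stats::approx(bottom, h$save_times, xout = 0.95)$y
  t95_analytic <- 1.3120 * (900e-6)^2 / 9e-10   # ~1.18e3 s
  expect_equal(t95, t95_analytic, tolerance = 0.05)
})

test_that("sphere-in-bath transient centre matches the series solution", {
  R <- 250e-6; D <- 9e-10; dr <- 5
  dom <- sphere_in_bath_domain(250, 100, dr, dr)
  sp <- species_params("probe", D_medium = 1e-6, D_tissue = D)
  tt <- c(0.1, 0.3, 0.5) * R^2 / D
  h <- simulate_well_transport(dom, sp, 1, t_end = max(tt), dt = 0.1,
                               save_times = c(0, tt))
  # finite volumes put the Dirichlet surface half a cell beyond the mask
  R_eff <- R + dr / 2 * 1e-6
  jz <- round(350 / dr)
  for (k in 1:3) {
    Fo <- D * tt[k] / R_eff^2
    expect_equal(h$frames[1, jz, k + 1], sphere_centre(Fo),
                 tolerance = 0.02)
  }
})

test_that("steady-state time decreases for smaller tissue (slower-in-tissue dye)", {
  sp <- species_params("dye", D_medium = 9e-10, D_tissue = 6e-10)
  t_small <- time_to_steady_state(
    simulate_well_transport(well_domain(tissue_model("sphere", 250),
                                        dr_um = 12.5, dz_um = 12.5),
                            sp, 1, 2500, 2))
  t_large <- time_to_steady_state(
    simulate_well_transport(well_domain(tissue_model("sphere", 500),
                                        dr_um = 12.5, dz_um = 12.5),
                            sp, 1, 2500, 2))
  expect_lt(t_small, t_large)
})

test_that("time_to_steady_state handles non-crossing and interpolation", {
  dom <- well_domain(tissue_model("sphere", 500), dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), 1, t_end = 60, dt = 2)
  t_na <- time_to_steady_state(h)
  expect_true(is.na(t_na))
  expect_match(attr(t_na, "message"), "not reached")
  h2 <- simulate_well_transport(dom, reagent_species(), 1, t_end = 1500, dt = 2)
  tss <- time_to_steady_state(h2)
  # interpolated crossing: tighter threshold must come later
  expect_lt(time_to_steady_state(h2, 0.90), tss)
})

test_that("maximum principle: conservative species never exceeds the boundary", {
  dom <- well_domain(tissue_model("cylinder", 500, 350),
                     dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), 1, t_end = 1200, dt = 5)
  expect_true(all(h$frames[!is.na(h$frames)] <= 1 + 1e-9))
  expect_true(all(h$frames[!is.na(h$frames)] >= -1e-12))
})

test_that("concentration is continuous across the medium-tissue interface", {
  # with equal diffusivities the interface must be invisible: the field in
  # a well with tissue equals the field of the empty well
  d1 <- well_domain(tissue_model("sphere", 500), dr_um = 25, dz_um = 25)
  d0 <- well_domain(tissue = NULL, dr_um = 25, dz_um = 25)
  h1 <- simulate_well_transport(d1, reagent_species(), 1, 600, 5)
  h0 <- simulate_well_transport(d0, reagent_species(), 1, 600, 5)
  expect_equal(h1$frames, h0$frames, tolerance = 1e-10)
})

test_that("mesh refinement leaves the steady-state time within 5%", {
  sp <- species_params("dye", D_medium = 9e-10, D_tissue = 6e-10)
  t_c <- time_to_steady_state(
    simulate_well_transport(well_domain(tissue_model("sphere", 500),
                                        dr_um = 25, dz_um = 25),
                            sp, 1, 2500, 2))
  t_f <- time_to_steady_state(
    simulate_well_transport(well_domain(tissue_model("sphere", 500),
                                        dr_um = 12.5, dz_um = 12.5),
                            sp, 1, 2500, 2))
  expect_equal(t_c, t_f, tolerance = 0.05)
})

test_that("mass balance closes and the explicit scheme guards its step", {
  dom <- well_domain(tissue_model("sphere", 500), dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), 1, 600, 5)
  expect_lt(h$mass$closure, 0.02)
  expect_error(simulate_well_transport(dom, reagent_species(), 1, 60, dt = 5,
                                       scheme = "explicit"),
               "dt <=")
  # explicit and implicit agree where both are stable
  dt_ok <- 0.25 * (25e-6)^2 / 9e-10 * 0.9
  he <- simulate_well_transport(dom, reagent_species(), 1, 60, dt = dt_ok,
                                scheme = "explicit")
  hi <- simulate_well_transport(dom, reagent_species(), 1, 60, dt = dt_ok)
  expect_equal(he$frames[, , dim(he$frames)[3]],
               hi$frames[, , dim(hi$frames)[3]], tolerance = 0.02)
})

test_that("dye accumulation is linear in time on a saturated field", {
  dom <- well_domain(tissue = NULL, mixed_depth_um = 900,
                     dr_um = 25, dz_um = 25)
  h <- simulate_well_transport(dom, reagent_species(), 1, t_end = 3 * 3600,
                               dt = 60, save_times = seq(0, 3 * 3600, 300))
  fi3 <- dye_accumulation(h, 1e-4, 3 * 3600)$mean_fi
  fi2 <- dye_accumulation(h, 1e-4, 2 * 3600)$mean_fi
  expect_equal(fi3 / fi2, 1.5, tolerance = 0.01)
  expect_error(dye_accumulation(h, -1, 3600), "non-negative")
  expect_error(dye_accumulation(h, 1e-4, 4 * 3600), "exceeds")
  # zero concentration -> zero FI
  h0 <- simulate_well_transport(dom, reagent_species(), 0, 600, 10)
  expect_equal(dye_accumulation(h0, 1e-4, 600)$mean_fi, 0)
})

test_that("longer incubation accumulates more dye in every tissue voxel", {
  dom <- well_domain(tissue_model("sphere", 500), dr_um = 25, dz_um = 25)
  sp <- species_params("dye", D_medium = 9e-10, D_tissue = 6e-10)
  h <- simulate_well_transport(dom, sp, 1, t_end = 3 * 3600, dt = 60,
                               save_times = seq(0, 3 * 3600, 300))
  B3 <- dye_accumulation(h, 1e-4, 3 * 3600)
  B2 <- dye_accumulation(h, 1e-4, 2 * 3600)
  tis <- h$tissue
  expect_true(all(B3$B[tis] > B2$B[tis]))
  expect_gt(B3$mean_fi, B2$mean_fi)
})
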