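test_that("per-aperture rates follow the aspiration ratio arithmetic", {
  expect_equal(flow_op$Q_asp_uLs, 1.4 * 9 * 0.5 / 16)  # 0.39375
  expect_equal(flow_op$total_inj_uLs, 4.5)
  expect_equal(flow_op$total_asp_uLs, 6.3)  # 1.4 x total injection
  # conservation invariant holds exactly
  expect_equal(flow_op$Q_asp_uLs * 16, 1.4 * 0.5 * 9)
  pair <- per_aperture_rates(pcd_geometry(1, 1), 0.5, 1.0)
  # 1 source + 4 corner sinks at ratio 1: per-sink rate = Q/4; a symmetric
  # single source/sink pair keeps the full rate
  expect_equal(pair$Q_asp_uLs * 4, 0.5)
  expect_error(per_aperture_rates(geom, -1, 1.4), "positive")
  expect_error(per_aperture_rates(geom, 0.5, 0), "positive")
})

test_that("an isolated source gives the closed-form radial velocity", {
  # Q/(2 pi r h): 0.5 uL/s at r = 1 mm under a 200 um gap
  g1 <- pcd_geometry(1, 1, gap_height_um = 200)
  ap <- pcdscreen:::aperture_table(g1, per_aperture_rates(g1, 0.5, 1))
  src <- ap[ap$sign > 0, ]
  v <- pcdscreen:::hs_velocity(src$x + 1e-3, src$y, src)
  expect_equal(v$u, 0.5e-9 / (2 * pi * 1e-3 * 200e-6), tolerance = 1e-12)
  expect_equal(v$v, 0, tolerance = 1e-15)
})

test_that("superposition matches brute-force term-by-term summation", {
  ap <- pcdscreen:::aperture_table(geom, flow_op)
  set.seed(7)
  px <- runif(100, -0.012, 0.012); py <- runif(100, -0.012, 0.012)
  v <- pcdscreen:::hs_velocity(px, py, ap)
  u_ref <- v_ref <- numeric(100)
  for (i in 1:100) {
    for (k in seq_len(nrow(ap))) {
      dx <- px[i] - ap$x[k]; dy <- py[i] - ap$y[k]
      r2 <- dx^2 + dy^2
      u_ref[i] <- u_ref[i] + ap$strength[k] * dx / r2
      v_ref[i] <- v_ref[i] + ap$strength[k] * dy / r2
    }
  }
  expect_equal(v$u, u_ref, tolerance = 1e-12)
  expect_equal(v$v, v_ref, tolerance = 1e-12)
})

test_that("symmetry: velocity on the perpendicular bisector of two equal sources", {
  g2 <- pcd_geometry(2, 1)   # two sources on the x axis
  ap <- pcdscreen:::aperture_table(g2, per_aperture_rates(g2, 0.5, 1))
  src <- ap[ap$sign > 0, ]
  expect_equal(mean(src$x), 0)
  v <- pcdscreen:::hs_velocity(rep(0, 5), c(-2, -1, 0.5, 1, 3) * 1e-3, src)
  expect_equal(v$u, rep(0, 5), tolerance = 1e-18)
})

test_that("wall shear follows the plane-Poiseuille formula and its scalings", {
  # 6 mu u / h arithmetic
  expect_equal(6 * 7e-4 * 1e-3 / 200e-6, 0.021)
  field <- velocity_field(geom, flow_op, flow_config(resolution_per_mm = 4))
  ws <- wall_shear_stress(field)
  expect_lt(ws$max_tau_Pa, 1)          # physiologically safe bound
  expect_gt(ws$safety_factor, 1)
  expect_true(all(ws$tau >= 0, na.rm = TRUE))
  # zero flow -> zero shear
  expect_equal(6 * field$cfg$viscosity_Pa_s * 0 / 200e-6, 0)
  # linearity: doubling Q doubles u and tau pointwise
  f2 <- velocity_field(geom, per_aperture_rates(geom, 1.0, 1.4),
                       flow_config(resolution_per_mm = 4))
  expect_equal(f2$u, 2 * field$u, tolerance = 1e-12)
  ws2 <- wall_shear_stress(f2)
  expect_equal(ws2$max_tau_Pa, 2 * ws$max_tau_Pa, tolerance = 1e-12)
  # tau ~ 1/h^2 at fixed Q
  gh <- pcd_geometry(gap_height_um = 400)
  wsh <- wall_shear_stress(velocity_field(gh, flow_op,
                                          flow_config(resolution_per_mm = 4)))
  expect_equal(ws$max_tau_Pa / wsh$max_tau_Pa, 4, tolerance = 0.01)
  # provenance check
  expect_error(wall_shear_stress(field, flow_config(viscosity_Pa_s = 1e-3)),
               "does not match")
})

test_that("net flux through an enclosing contour balances the source/sink deficit", {
  ap <- pcdscreen:::aperture_table(geom, flow_op)
  h_m <- geom$gap_height_um * 1e-6
  R <- 15e-3
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  v <- pcdscreen:::hs_velocity(R * cos(th), R * sin(th), ap)
  flux <- sum(v$u * cos(th) + v$v * sin(th)) * R * (2 * pi / 2000)
  expected <- (4.5e-9 - 6.3e-9) / h_m   # (sum Q_inj - sum Q_asp) / h
  expect_equal(flux, expected, tolerance = 0.01)
})

test_that("field evaluation masks aperture singularities instead of failing", {
  field <- velocity_field(geom, flow_op, flow_config(resolution_per_mm = 4))
  expect_true(any(is.na(field$u)))     # exclusion disks masked
  expect_true(all(is.finite(field$u[!is.na(field$u)])))
  expect_error(velocity_field(geom, flow_op,
                              flow_config(resolution_per_mm = 1)),
               "resolution")
})
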