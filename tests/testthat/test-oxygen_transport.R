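test_that("layer and stack constructors enforce their invariants", {
  expect_error(diffusion_layer("glass", 100, 0, "glass"), "no-flux")
  expect_error(diffusion_layer("x", -1, 1e-5, "water"), "positive")
  st <- default_layer_stack()
  expect_equal(st$total_thickness_m, 315e-6)
  expect_error(gas_protocol(c(0, 0), c(160, 0)), "increasing")
  expect_error(gas_protocol(0, 200), "160")
})

test_that("equilibrium initial condition is preserved", {
  st <- default_layer_stack()
  sim <- simulate_gas_switch(st, gas_protocol(0, 160), t_end_s = 5,
                             dz_um = 3, dt_s = 0.5)
  expect_equal(max(abs(sim$conc - 160)), 0, tolerance = 1e-10)
})

test_that("after a downward switch the field relaxes monotonically to zero", {
  st <- default_layer_stack()
  sim <- simulate_gas_switch(st, gas_protocol(0, 0), t_end_s = 400,
                             dz_um = 3, dt_s = 0.5, initial_mmhg = 160)
  # monotone in time at every node
  expect_true(all(diff(sim$conc) <= 1e-9))
  # long-time limit: everything drains through the single Dirichlet sink
  expect_lt(max(sim$conc[nrow(sim$conc), ]), 1)
})

test_that("solver matches the analytic single-slab cosine series", {
  L_um <- 200
  slab <- layer_stack(list(diffusion_layer("w", L_um, 4e-5, "water")))
  sim <- simulate_gas_switch(slab, gas_protocol(0, 0), t_end_s = 10,
                             dz_um = 1, dt_s = 0.002, initial_mmhg = 160)
  D <- 4e-9
  for (t_probe in c(2, 5, 10)) {
    k <- which.min(abs(sim$time_s - t_probe))
    z_sel <- c(0, 50, 100, 150) * 1e-6
    j <- vapply(z_sel * 1e6, function(z) which.min(abs(sim$z_um - z)), 0L)
    exact <- slab_series(z_sel, sim$time_s[k], L_um * 1e-6, D)
    expect_equal(sim$conc[k, j], exact, tolerance = 5e-3)
  }
})

test_that("sealed-stack mode conserves the integrated concentration", {
  st <- default_layer_stack()
  sim <- simulate_gas_switch(st, gas_protocol(0, 0), t_end_s = 20,
                             dz_um = 3, dt_s = 0.5, initial_mmhg = 100,
                             conserving = TRUE)
  w <- rep(1, ncol(sim$conc))
  w[c(1, length(w))] <- 0.5
  totals <- as.vector(sim$conc %*% w)
  expect_lt(max(abs(totals / totals[1] - 1)), 1e-10)
})

test_that("explicit scheme cross-validates the implicit default", {
  slab <- layer_stack(list(diffusion_layer("w", 100, 4e-5, "water")))
  # explicit stability requires dt <= dz^2 / (2 D)
  expect_error(simulate_gas_switch(slab, gas_protocol(0, 0), t_end_s = 2,
                                   dz_um = 2, dt_s = 0.01,
                                   scheme = "explicit"),
               "unstable")
  si <- simulate_gas_switch(slab, gas_protocol(0, 0), t_end_s = 2,
                            dz_um = 2, dt_s = 2e-4)
  se <- simulate_gas_switch(slab, gas_protocol(0, 0), t_end_s = 2,
                            dz_um = 2, dt_s = 2e-4, scheme = "explicit")
  k <- nrow(si$conc)
  expect_equal(si$conc[k, ], se$conc[k, ], tolerance = 5e-3)
})

test_that("anoxia time is near the observed minute and scales diffusively", {
  st <- default_layer_stack()
  sim <- simulate_gas_switch(st, gas_protocol(0, 0), t_end_s = 200,
                             initial_mmhg = 160)
  t1 <- time_to_anoxia(sim)
  expect_gt(t1, 30)   # within a factor 2 of the observed ~60 s
  expect_lt(t1, 120)
  # doubling all thicknesses quadruples the diffusion time (L^2 scaling)
  st2 <- layer_stack(lapply(st$layers, function(l)
    diffusion_layer(l$name, l$thickness_m * 2e6, l$d_m2_s * 1e4,
                    l$material)))
  sim2 <- simulate_gas_switch(st2, gas_protocol(0, 0), t_end_s = 800,
                              dz_um = 2, initial_mmhg = 160)
  t2 <- time_to_anoxia(sim2)
  expect_equal(t2 / t1, 4, tolerance = 0.05)
  # grid convergence: halving the spacing moves the estimate < 2%
  simh <- simulate_gas_switch(st, gas_protocol(0, 0), t_end_s = 200,
                              dz_um = 0.5, initial_mmhg = 160)
  expect_lt(abs(time_to_anoxia(simh) / t1 - 1), 0.02)
  # threshold at the initial tension crosses immediately
  expect_equal(time_to_anoxia(sim, threshold_mmhg = 160), 0)
  # span too short to cross reports a sentinel
  sim_short <- simulate_gas_switch(st, gas_protocol(0, 0), t_end_s = 5,
                                   dz_um = 3, initial_mmhg = 160)
  expect_true(is.na(time_to_anoxia(sim_short)))
})

test_that("Stern-Volmer two-point calibration inverts intensities", {
  cal <- stern_volmer_calibrate(1000, 400)
  expect_equal(cal$k_sv_per_mmhg, 0.009375)
  expect_equal(cal$intensity_to_po2(500), 106.67, tolerance = 1e-4)
  expect_equal(cal$intensity_to_po2(1000), 0)
  expect_equal(cal$intensity_to_po2(400), 160, tolerance = 1e-12)
  expect_warning(cal$intensity_to_po2(1100), "clamping")
  expect_error(cal$intensity_to_po2(-1), "positive")
  expect_error(stern_volmer_calibrate(400, 1000), "quenches")
  # the linear alternative agrees at the calibration endpoints only
  lin <- linear_calibrate(1000, 400)
  expect_equal(lin$intensity_to_po2(1000), 0)
  expect_equal(lin$intensity_to_po2(400), 160)
  # collisional quenching is convex: mid-range intensities map to
  # lower tensions than the linear interpolant
  expect_lt(cal$intensity_to_po2(700), lin$intensity_to_po2(700))
})
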