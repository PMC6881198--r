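test_that("average shear rate follows the midline-velocity definition", {
  expect_equal(average_shear_rate(750), 100)
  expect_equal(average_shear_rate(0), 0)
  expect_equal(average_shear_rate(3500), 466.67, tolerance = 1e-4)
  expect_error(average_shear_rate(100, 0), "positive")
})

test_that("velocity-to-flow conversion uses the laminar profile factor", {
  g <- channel_geometry(15e-6, 15e-6, 0.02, "square")
  expect_equal(experimental_flow_from_velocity(3.5e-3, g, 0.477),
               3.756e-13, tolerance = 1e-3)
  expect_equal(experimental_flow_from_velocity(3.5e-3, g, 1),
               3.5e-3 * 15e-6 * 15e-6)
  expect_error(experimental_flow_from_velocity(1e-3, g, 0), "0, 1")
})

test_that("default profile factor matches the square-duct Poiseuille ratio", {
  # independent finite-difference solve of the duct Poisson problem
  ratio <- square_duct_profile_ratio(61)
  expect_equal(ratio, 0.477, tolerance = 2e-3)
  expect_equal(viscometry_settings()$profile_factor, 0.4771)
})

test_that("total flow splits across the parallel branches by conductance", {
  net <- example_network()
  # symmetric branches, Newtonian: flow doubles
  sym <- device_network(
    hydraulic_resistor("inlet_resistor", c_per_m3 = 2e15),
    hydraulic_resistor("bypass", c_per_m3 = 1e16),
    hydraulic_resistor("experimental", c_per_m3 = 1e16))
  expect_equal(total_flow(1e-13, sym, B = 1), 2e-13)
  # infinitely viscous bypass carries nothing
  expect_equal(total_flow(1e-13, net, B = 1e12), 1e-13, tolerance = 1e-6)
  expect_equal(total_flow(1e-13, net, B = 1), 3.5e-13)
})

test_that("effective viscosity inverts the forward network relation", {
  net <- example_network()
  # Newtonian round trip at the worked operating point
  r <- network_resistance(net, 0.004, 0.004, 0.004)
  expect_equal(effective_viscosity(r * 1e-12, 1e-12, net), 0.004,
               tolerance = 1e-12)
  # Newtonian identity over random positive constants and viscosities
  set.seed(42)
  for (i in 1:20) {
    cs <- 10^stats::runif(3, 14, 17)
    nw <- device_network(
      hydraulic_resistor("inlet_resistor", c_per_m3 = cs[1]),
      hydraulic_resistor("bypass", c_per_m3 = cs[2]),
      hydraulic_resistor("experimental", c_per_m3 = cs[3]))
    eta0 <- 10^stats::runif(1, -3, -1)
    q <- 10^stats::runif(1, -14, -12)
    dp <- q * network_resistance(nw, eta0, eta0, eta0)
    expect_equal(effective_viscosity(dp, q, nw), eta0,
                 tolerance = 1e-12)
  }
  # linear in the pressure drop at fixed flow
  expect_equal(effective_viscosity(2 * r * 1e-12, 1e-12, net),
               2 * effective_viscosity(r * 1e-12, 1e-12, net))
  expect_error(effective_viscosity(-1, 1e-12, net), "positive")
})

test_that("noiseless Newtonian trace inverts to a flat rheogram", {
  net <- default_device_network()
  m <- noiseless_model(n_anchors = c(1, 1, 1),
                       k_multipliers = c(1, 1, 1))
  tr <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 3,
                       replicates = 1)
  rg <- quiet_infer(tr, net)
  expect_equal(rg$viscosity_pa_s, rep(0.012, nrow(rg)), tolerance = 1e-9)
  expect_lte(attr(rg, "diagnostics")[["92"]]$iterations, 3)
})

test_that("fixed-point inversion recovers the forward power-law oracle", {
  # forward: bracketed nonlinear root finding on the full network;
  # inverse: ratio-factor fixed point. Two independent routes.
  net <- default_device_network()
  for (n_gen in c(0.6, 0.8, 1.0)) {
    m <- noiseless_model(n_anchors = rep(n_gen, 3),
                         k_multipliers = c(1, 1, 1))
    tr <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 4,
                         replicates = 1)
    truth <- attr(tr, "truth")
    rg <- quiet_infer(tr, net)
    eta_true <- truth$K_pa_sn * truth$shear_rate_per_s^(truth$n - 1)
    expect_lt(max(abs(rg$viscosity_pa_s / eta_true - 1)), 0.01)
    fit <- fit_rheogram(rg)
    expect_lt(abs(fit$n - n_gen), 0.01)
  }
})

test_that("converged solution satisfies the network pressure balance", {
  net <- default_device_network()
  m <- noiseless_model()
  tr <- generate_trace(m, net, po2_levels_mmhg = c(92, 0), seed = 5,
                       replicates = 1)
  rg <- quiet_infer(tr, net)
  st <- viscometry_settings()
  for (po in c(92, 0)) {
    s <- rg[rg$po2_mmhg == po, ]
    diag <- attr(rg, "diagnostics")[[as.character(po)]]
    steps <- attr(tr, "truth")
    steps <- steps[steps$po2_mmhg == po, ]
    g3 <- net$experimental$geometry
    q_exp <- experimental_flow_from_velocity(steps$umax_um_s * 1e-6, g3,
                                             st$profile_factor)
    # flow is monotone in pressure, so both tables share the same order
    q_tot <- total_flow(q_exp, net, diag$B)
    eta3 <- s$viscosity_pa_s
    r_hyd <- network_resistance(net, diag$A * eta3, diag$B * eta3, eta3)
    resid <- abs(steps$pressure_pa - q_tot * r_hyd) / steps$pressure_pa
    expect_lt(max(resid), 1e-6)
  }
})

test_that("monotone pressure gives monotone flow for shear-thinning laws", {
  net <- default_device_network()
  for (n_gen in c(0.6, 0.9)) {
    q <- vapply(c(500, 2000, 8000, 20000), function(dp)
      forward_operating_point(dp, n_gen, 0.012, net)$q_exp, 0)
    expect_true(all(diff(q) > 0))
  }
})

test_that("degenerate traces are rejected with informative errors", {
  net <- default_device_network()
  m <- noiseless_model()
  tr <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 6,
                       replicates = 2)
  tr0 <- tr
  tr0$umax_um_s <- 0
  expect_error(quiet_infer(tr0, net), "zero")
  tr2 <- tr[tr$pressure_pa %in% sort(unique(tr$pressure_pa))[1:2], ]
  expect_error(quiet_infer(tr2, net), "3 pressure steps")
  trneg <- tr
  trneg$pressure_pa[1] <- -5
  expect_error(quiet_infer(trneg, net), "positive")
})

test_that("replicate scatter propagates to the rheogram SD", {
  net <- default_device_network()
  m <- build_blood_model(sickle_composition(),
                         blood_model_params(noise_cv = 0.05))
  tr <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 7)
  rg <- quiet_infer(tr, net)
  expect_true(all(rg$sd_pa_s > 0))
  # relative SD of viscosity tracks the replicate velocity CV (~5%)
  expect_true(all(rg$sd_pa_s / rg$viscosity_pa_s < 0.15))
  expect_equal(rg$shear_stress_pa,
               rg$viscosity_pa_s * rg$shear_rate_per_s, tolerance = 1e-12)
})
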