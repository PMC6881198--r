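test_that("blood model interpolates the flow-behavior-index anchors", {
  m <- build_blood_model(sample_composition(hbs = 1, hba = 0))
  expect_equal(m$n_fun(92), 0.76)
  expect_equal(m$n_fun(46), 0.74)
  expect_equal(m$n_fun(0), 0.87)
  expect_equal(m$n_fun(23), 0.805)     # midpoint of the 46 and 0 anchors
  expect_equal(m$n_fun(160), 0.76)     # constant above the top anchor
  # viscosity at 100 /s strictly increases with deoxygenation
  eta100 <- m$k_fun(c(92, 46, 0)) * 100^(m$n_fun(c(92, 46, 0)) - 1)
  expect_true(all(diff(eta100) > 0))
})

test_that("healthy blood is oxygen independent", {
  m <- build_blood_model(sample_composition(hbs = 0, hba = 1))
  po2 <- c(0, 20, 46, 92, 160)
  expect_equal(m$n_fun(po2), rep(m$n_fun(92), 5))
  expect_equal(m$k_fun(po2), rep(m$k_fun(92), 5))
})

test_that("transfusion mixing follows the hemoglobin mass balance", {
  s <- sample_composition(hbs = 1, hba = 0, mchc_g_dl = 33)
  d <- sample_composition(hbs = 0, hba = 1, mchc_g_dl = 33)
  # equal MCHC: mass fraction equals volume fraction
  expect_equal(mix_transfusion(s, d, 0.30)$hbs, 0.30)
  expect_equal(mix_transfusion(s, d, 0)$hbs, d$hbs)
  expect_equal(mix_transfusion(s, d, 0)$mchc_g_dl, d$mchc_g_dl)
  # unequal MCHC worked example, inverted by bisection
  s2 <- sample_composition(hbs = 0.95, hba = 0.05, mchc_g_dl = 32)
  d2 <- sample_composition(hbs = 0, hba = 1, mchc_g_dl = 34)
  v <- transfusion_volume_fraction(s2, d2, 0.25)
  expect_equal(v, 0.2751, tolerance = 1e-3)
  expect_equal(mix_transfusion(s2, d2, v)$hbs, 0.25, tolerance = 1e-9)
  expect_error(mix_transfusion(s2, sample_composition(hct = 0.45), 0.5),
               "HCT")
})

test_that("mixing conserves total hemoglobin mass per unit volume", {
  set.seed(21)
  for (i in 1:25) {
    s <- sample_composition(hbs = runif(1, 0.6, 1), hba = 0,
                            mchc_g_dl = runif(1, 28, 36))
    d <- sample_composition(hbs = 0, hba = 1,
                            mchc_g_dl = runif(1, 30, 37))
    v <- runif(1)
    mx <- mix_transfusion(s, d, v)
    mass_in <- v * s$mchc_g_dl * (s$hbs + s$hba + s$hbf) +
      (1 - v) * d$mchc_g_dl * (d$hbs + d$hba + d$hbf)
    mass_out <- mx$mchc_g_dl * (mx$hbs + mx$hba + mx$hbf)
    expect_equal(mass_out, mass_in, tolerance = 1e-12)
    # HbS mass specifically
    expect_equal(mx$mchc_g_dl * mx$hbs, v * s$mchc_g_dl * s$hbs,
                 tolerance = 1e-12)
  }
})

test_that("mixture material law interpolates with sensitivity weighting", {
  comp <- sickle_composition()
  par <- blood_model_params()
  sick <- build_blood_model(sample_composition(hbs = 1, hba = 0), par)
  heal <- build_blood_model(sample_composition(hbs = 0, hba = 1), par)
  expect_equal(mixture_blood_model(sick, heal, 0)$n_fun(0),
               heal$n_fun(0))
  expect_equal(mixture_blood_model(sick, heal, 1)$n_fun(0),
               sick$n_fun(0))
  # s = 2, f = 0.5: weight 0.25 of the endpoint gap
  m <- mixture_blood_model(sick, heal, 0.5, sensitivity = 2)
  gap <- sick$n_fun(0) - heal$n_fun(0)
  expect_equal(m$n_fun(0) - heal$n_fun(0), 0.25 * gap, tolerance = 1e-12)
  expect_error(mixture_blood_model(sick, heal, 0.5, -1), ">= 0")
})

test_that("traces are deterministic given the seed", {
  net <- default_device_network()
  m <- build_blood_model(sickle_composition())
  t1 <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 9)
  t2 <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_trace(m, net, po2_levels_mmhg = 92, seed = 10)
  expect_false(identical(t1$umax_um_s, t3$umax_um_s))
  expect_error(generate_trace(m, net, po2_levels_mmhg = 92), "seed")
})

test_that("Newtonian forward model is linear in pressure", {
  net <- default_device_network()
  m <- noiseless_model(n_anchors = c(1, 1, 1), k_multipliers = c(1, 1, 1))
  dp <- c(1000, 2000, 4000, 8000)
  tr <- generate_trace(m, net, pressure_steps_pa = dp,
                       po2_levels_mmhg = 92, seed = 12, replicates = 1)
  u <- tr$umax_um_s
  expect_equal(u / u[1], dp / dp[1], tolerance = 1e-8)
})

test_that("single-resistor power-law forward matches the duct closed form", {
  # make the inlet and bypass negligible: flow ~ dp^(1/n) exactly
  net <- device_network(
    hydraulic_resistor("inlet_resistor",
                       channel_geometry(15e-6, 15e-6, 1e-9, "square")),
    hydraulic_resistor("bypass",
                       channel_geometry(15e-6, 15e-6, 1e6, "square")),
    hydraulic_resistor("experimental",
                       channel_geometry(15e-6, 15e-6, 0.02, "square")))
  n_gen <- 0.8
  dp <- c(1000, 3000, 9000, 27000)
  u <- vapply(dp, function(p)
    forward_operating_point(p, n_gen, 0.012, net)$umax_um_s, 0)
  slope <- stats::coef(stats::lm(log(u) ~ log(dp)))[2]
  expect_equal(unname(slope), 1 / n_gen, tolerance = 1e-6)
})

test_that("cohort generation is reproducible and centred on the anchors", {
  spec <- cohort_spec(seed = 31, between_sd = c(0, 0, 0))
  co <- generate_cohort(spec)
  expect_length(co$traces, 9)
  # zero between-subject SD: all patients share the generating truth
  expect_equal(max(tapply(co$truth$n_true, co$truth$po2_mmhg,
                          function(x) diff(range(x)))), 0)
  expect_identical(generate_cohort(spec)$truth, co$truth)
  # sampled anchors stay within 3 SE of the cohort means
  spec2 <- cohort_spec(seed = 32)
  co2 <- generate_cohort(spec2)
  t0 <- co2$truth[co2$truth$po2_mmhg == 0, "n_true"]
  expect_lt(abs(mean(t0) - 0.87), 3 * 0.056 / sqrt(9))
})

test_that("pipeline on healthy traces shows no oxygen dependence", {
  net <- default_device_network()
  m <- build_blood_model(sample_composition(hbs = 0, hba = 1),
                         blood_model_params(noise_cv = 0.05))
  tr <- generate_trace(m, net, po2_levels_mmhg = c(92, 0), seed = 14)
  steps <- summarise <- aggregate(umax_um_s ~ po2_mmhg + pressure_pa,
                                  tr, mean)
  v_ox <- steps$umax_um_s[steps$po2_mmhg == 92]
  v_de <- steps$umax_um_s[steps$po2_mmhg == 0]
  fvc <- fractional_velocity_change(v_ox, v_de)
  # |fvc| bounded by ~3x the replicate-mean noise SE
  se <- 0.05 / sqrt(18) * sqrt(2)
  expect_true(all(abs(fvc) < 3.5 * se))
})

test_that("full-loop recovery of each patient's generating exponent", {
  spec <- cohort_spec(n_patients = 4, seed = 33)
  co <- generate_cohort(spec)
  fits <- cohort_fits(co)
  mg <- merge(fits, co$truth, by = c("patient", "po2_mmhg"))
  err <- mg$n - mg$n_true
  expect_lt(abs(mean(err)), 0.01)
  # RMSE bounded by the noise-predicted scale: per-point stress CV
  # ~ cv/sqrt(18) over an 8-point two-decade design
  expect_lt(sqrt(mean(err^2)), 0.02)
})
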