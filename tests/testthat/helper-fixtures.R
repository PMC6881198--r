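# Shared fixtures: small networks, material laws, and independent oracles
# used across the test files.

# Network with the constants used in the worked algebraic examples.
example_network <- function() {
  device_network(
    hydraulic_resistor("inlet_resistor", c_per_m3 = 2e15),
    hydraulic_resistor("bypass", c_per_m3 = 4e15),
    hydraulic_resistor("experimental", c_per_m3 = 1e16)
  )
}

sickle_composition <- function() {
  sample_composition(hbs = 0.95, hba = 0.02, hbf = 0.03)
}

noiseless_model <- function(...) {
  build_blood_model(sickle_composition(),
                    blood_model_params(noise_cv = 0, ...))
}

quiet_infer <- function(...) {
  suppressMessages(infer_rheogram(...))
}

# Independent oracle for the square-duct mean/max velocity ratio:
# finite-difference solve of -lap(u) = 1 on the unit square with zero
# walls, no shared code with the package.
square_duct_profile_ratio <- function(n = 41) {
  h <- 1 / (n + 1)
  one <- diag(n)
  d2 <- diag(-2, n)
  d2[cbind(1:(n - 1), 2:n)] <- 1
  d2[cbind(2:n, 1:(n - 1))] <- 1
  lap <- (kronecker(one, d2) + kronecker(d2, one)) / h^2
  u <- solve(-lap, rep(1, n * n))
  # integral over the section: interior nodes carry weight h^2 and the
  # boundary ring is zero, so the sectional mean is sum(u) h^2
  (sum(u) * h^2) / max(u)
}

# Analytic cosine-series solution for a uniform slab, initial value c0,
# no-flux at z = 0, Dirichlet 0 at z = L.
slab_series <- function(z, t, L, D, c0 = 160, terms = 200) {
  m <- 0:(terms - 1)
  lam <- (2 * m + 1) * pi / (2 * L)
  coef <- c0 * 4 / pi * (-1)^m / (2 * m + 1)
  vapply(seq_along(z), function(i) {
    sum(coef * cos(lam * z[i]) * exp(-D * lam^2 * t))
  }, 0)
}
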