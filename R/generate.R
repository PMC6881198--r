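# Forward model of the device and synthetic trace/cohort generation.
#
# The forward problem is the nonlinear counterpart of the inversion: given
# a driving pressure and a power-law material law, find the flow split
# through the resistor network such that both parallel branches see the
# same pressure drop and the series sum matches the applied pressure,
# with each section's viscosity evaluated at its own average shear rate.
# It is solved by bracketed root finding on the experimental-channel flow
# and serves as the independent oracle for the fixed-point inversion.

# Shear-rate-per-flow coefficient a such that gamma = a * Q for a channel:
# gamma = umax / (h/2), umax = Q / (f h w).
shear_coeff <- function(geometry, profile_factor) {
  1 / (profile_factor * geometry$height_m * geometry$width_m *
         geometry$height_m / 2)
}

#' Solve the forward network problem at one operating point
#'
#' Given the total driving pressure, a power-law material law
#' (tau = K gamma^n applied in every section at that section's shear
#' rate), and the device network, finds the experimental-channel flow by
#' bracketed root finding on the pressure balance.
#'
#' @param dp_total_pa Driving pressure (Pa, > 0).
#' @param n,K_pa_sn Power-law exponent and consistency index.
#' @param network A [device_network()] with resistor geometries.
#' @param profile_factor Mean/max laminar velocity ratio.
#' @param velocity_rule `"continuity"` (physical flow split; default) or
#'   `"area_proportional"` (sectional shear rates tied to the
#'   experimental channel by area ratios).
#' @return List: `q_exp`, `q_bypass`, `q_total` (m^3/s), `umax_um_s`,
#'   `shear_rate_per_s` in the experimental channel, and the achieved
#'   relative pressure residual.
#' @export
forward_operating_point <- function(dp_total_pa, n, K_pa_sn, network,
                                    profile_factor = 0.4771,
                                    velocity_rule = c("continuity",
                                                      "area_proportional")) {
  velocity_rule <- match.arg(velocity_rule)
  if (dp_total_pa <= 0) stop("pressure must be positive", call. = FALSE)
  g1 <- network$inlet_resistor$geometry
  g2 <- network$bypass$geometry
  g3 <- network$experimental$geometry
  if (is.null(g1) || is.null(g2) || is.null(g3))
    stop("forward solve requires resistor geometries", call. = FALSE)
  a1 <- shear_coeff(g1, profile_factor)
  a2 <- shear_coeff(g2, profile_factor)
  a3 <- shear_coeff(g3, profile_factor)
  area2 <- g2$height_m * g2$width_m
  area3 <- g3$height_m * g3$width_m

  eta <- function(gamma) K_pa_sn * gamma^(n - 1)

  # pressure implied by a trial experimental flow q3
  dp_of <- function(q3) {
    gamma3 <- a3 * q3
    dpar <- q3 * network$c3 * eta(gamma3)
    if (velocity_rule == "continuity") {
      # branch balance q2 c2 K (a2 q2)^(n-1) = dpar has the closed form
      q2 <- (dpar / (network$c2 * K_pa_sn * a2^(n - 1)))^(1 / n)
    } else {
      # bypass mean velocity tied to the experimental channel by area
      u2max <- (q3 / (profile_factor * area3)) * (area2 / area3)
      gamma2 <- u2max / (g2$height_m / 2)
      q2 <- dpar / (network$c2 * eta(gamma2))
    }
    qt <- q2 + q3
    gamma1 <- a1 * qt
    list(dp = qt * network$c1 * eta(gamma1) + dpar, q2 = q2, qt = qt)
  }

  f <- function(lq3) dp_of(10^lq3)$dp - dp_total_pa
  sol <- tryCatch(
    stats::uniroot(f, lower = -18, upper = -8, extendInt = "upX",
                   tol = 1e-14),
    error = function(e)
      stop("forward solve failed to bracket the flow at dp = ",
           dp_total_pa, " Pa (n = ", n, ", K = ", K_pa_sn, "): ",
           conditionMessage(e), call. = FALSE))
  q3 <- 10^sol$root
  parts <- dp_of(q3)
  umax <- q3 * a3 * g3$height_m / 2          # invert gamma3 = umax/(h/2)
  list(q_exp = q3, q_bypass = parts$q2, q_total = parts$qt,
       umax_um_s = umax * 1e6, shear_rate_per_s = a3 * q3,
       residual = abs(parts$dp - dp_total_pa) / dp_total_pa)
}

#' Default pressure-step protocol
#'
#' Eight logarithmically spaced driving pressures (Pa) spanning
#' experimental-channel average shear rates of roughly 20 to 500 /s for
#' the default oxygenated blood model, covering the 100 /s comparison
#' point.
#'
#' @return Numeric vector of pressures in Pa.
#' @export
default_pressure_steps <- function() {
  round(exp(seq(log(1000), log(25000), length.out = 8)))
}

#' Generate a synthetic velocity trace for one sample
#'
#' For each oxygen tension and pressure step, solves the forward network
#' problem with the sample's material law evaluated at that tension, then
#' emits replicate velocity captures with multiplicative Gaussian noise.
#'
#' @param model A `blood_model`.
#' @param network A [device_network()] with geometries.
#' @param pressure_steps_pa Driving pressures (Pa), default
#'   [default_pressure_steps()].
#' @param po2_levels_mmhg Oxygen tensions visited (default 92, 46, 0).
#' @param replicates Video captures per pressure step (default 18).
#' @param seed Integer seed; mandatory (every synthetic run must be
#'   reproducible).
#' @param dwell_s Wall-clock duration of one pressure step (default 30 s);
#'   replicate capture times fill the steady-state second half of the
#'   step.
#' @param settings A [viscometry_settings()] (profile factor and velocity
#'   rule used by the forward model).
#' @return A data frame of class `rheology_trace` with columns `time_s`,
#'   `pressure_pa`, `po2_mmhg`, `umax_um_s`, `replicate`, and the
#'   noiseless ground truth in `attr(, "truth")`.
#' @export
generate_trace <- function(model, network,
                           pressure_steps_pa = default_pressure_steps(),
                           po2_levels_mmhg = c(92, 46, 0),
                           replicates = 18, seed,
                           dwell_s = 30,
                           settings = viscometry_settings()) {
  stopifnot(inherits(model, "blood_model"))
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required for synthetic generation",
         call. = FALSE)
  if (!length(pressure_steps_pa))
    stop("pressure step list is empty", call. = FALSE)
  if (replicates < 1) stop("need at least one replicate", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  rows <- list()
  truth <- list()
  step_i <- 0
  for (po2 in po2_levels_mmhg) {
    n <- model$n_fun(po2)
    K <- model$k_fun(po2)
    for (dp in sort(pressure_steps_pa)) {
      step_i <- step_i + 1
      op <- forward_operating_point(dp, n, K, network,
                                    settings$profile_factor,
                                    settings$velocity_rule)
      t0 <- (step_i - 1) * dwell_s
      t_cap <- t0 + seq(dwell_s / 2, dwell_s, length.out = replicates)
      noise <- 1 + model$noise_cv * stats::rnorm(replicates)
      noise <- pmax(noise, 0.05)   # guard against negative velocities
      rows[[step_i]] <- data.frame(
        time_s = t_cap, pressure_pa = dp, po2_mmhg = po2,
        umax_um_s = op$umax_um_s * noise,
        replicate = seq_len(replicates))
      truth[[step_i]] <- data.frame(
        po2_mmhg = po2, pressure_pa = dp, umax_um_s = op$umax_um_s,
        shear_rate_per_s = op$shear_rate_per_s, n = n, K_pa_sn = K)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, truth = do.call(rbind, truth), seed = seed,
            class = c("rheology_trace", "data.frame"))
}

#' Cohort specification for synthetic patient generation
#'
#' @param n_patients Number of patients (default 9, the device cohort
#'   size).
#' @param seed Mandatory integer seed.
#' @param between_sd Between-subject SDs of the flow-behavior-index
#'   anchors at 92, 46, 0 mm Hg (default 0.075, 0.049, 0.056, the
#'   observed cohort SDs).
#' @param pressure_steps_pa Driving pressures per patient.
#' @param replicates Video captures per step (default 18).
#' @param po2_levels_mmhg Oxygen tensions visited (default 92, 46, 0).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 9, seed,
                        between_sd = c(0.075, 0.049, 0.056),
                        pressure_steps_pa = default_pressure_steps(),
                        replicates = 18,
                        po2_levels_mmhg = c(92, 46, 0)) {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  stopifnot(n_patients >= 1, replicates >= 1, all(between_sd >= 0))
  structure(list(n_patients = as.integer(n_patients), seed = seed,
                 between_sd = between_sd,
                 pressure_steps_pa = pressure_steps_pa,
                 replicates = as.integer(replicates),
                 po2_levels_mmhg = po2_levels_mmhg),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient flow-behavior-index anchors from normal
#' distributions centred on the cohort anchors with the specified
#' between-subject SDs (truncated to (0.3, 1.3)), then generates one
#' velocity trace per patient. The generating truth is returned alongside
#' the traces so parameter-recovery tests can close the loop.
#'
#' @param spec A [cohort_spec()].
#' @param params Base [blood_model_params()] for the cohort.
#' @param composition Per-patient [sample_composition()] (default:
#'   untransfused sickle blood at 25% HCT).
#' @param network A [device_network()].
#' @param settings A [viscometry_settings()].
#' @return List of class `synthetic_cohort`: `traces` (list of
#'   `rheology_trace`), `truth` (data frame patient x oxygen tension with
#'   the drawn n and K), and the spec.
#' @export
generate_cohort <- function(spec, params = blood_model_params(),
                            composition = sample_composition(hbs = 0.95,
                                                             hba = 0.02,
                                                             hbf = 0.03),
                            network = default_device_network(),
                            settings = viscometry_settings()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(spec$between_sd) != length(params$n_po2_mmhg))
    stop("between_sd must match the number of anchor tensions",
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1, spec$n_patients)

  draw_anchor <- function(mean, sd) {
    if (sd == 0) return(mean)
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > 0.3 && x < 1.3) return(x)
    }
  }

  traces <- vector("list", spec$n_patients)
  truth <- list()
  for (i in seq_len(spec$n_patients)) {
    anchors_i <- mapply(draw_anchor, params$n_anchors, spec$between_sd)
    params_i <- params
    params_i$n_anchors <- anchors_i
    model_i <- build_blood_model(composition, params_i)
    traces[[i]] <- generate_trace(
      model_i, network, spec$pressure_steps_pa,
      po2_levels_mmhg = spec$po2_levels_mmhg,
      replicates = spec$replicates, seed = patient_seeds[i],
      settings = settings)
    truth[[i]] <- data.frame(patient = i,
                             po2_mmhg = spec$po2_levels_mmhg,
                             n_true = model_i$n_fun(spec$po2_levels_mmhg),
                             k_true = model_i$k_fun(spec$po2_levels_mmhg))
  }
  structure(list(traces = traces, truth = do.call(rbind, truth),
                 spec = spec),
            class = "synthetic_cohort")
}

#' Run the inference pipeline over a cohort
#'
#' Inverts every patient trace to rheograms and fits power laws,
#' returning the per-patient, per-tension flow behavior indices in long
#' form - the table the cohort statistics operate on.
#'
#' @param cohort A `synthetic_cohort` (or a list of traces).
#' @param network A [device_network()].
#' @param settings A [viscometry_settings()].
#' @return Data frame: `patient`, `po2_mmhg`, `n`, `K_pa_sn`, `r2`.
#' @export
cohort_fits <- function(cohort, network = default_device_network(),
                        settings = viscometry_settings()) {
  traces <- if (inherits(cohort, "synthetic_cohort")) cohort$traces
            else cohort
  rows <- lapply(seq_along(traces), function(i) {
    rg <- infer_rheogram(traces[[i]], network, settings)
    ft <- fit_rheogram(rg)
    cbind(patient = i, ft[c("po2_mmhg", "n", "K_pa_sn", "r2")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
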