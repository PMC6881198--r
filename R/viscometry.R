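# Inversion of pressure-step velocity data through the resistor network:
# effective viscosity vs average shear rate per oxygen tension.
#
# The measured quantity is the maximum midline velocity in the experimental
# channel. The unknowns are the three sectional effective viscosities; they
# are reduced to one (eta3, the experimental section) via the ratio factors
# A = eta1/eta3 and B = eta2/eta3, which for a power-law fluid equal the
# sectional shear-rate ratios raised to (n - 1). A and B are not known in
# advance because n is itself the quantity being estimated, hence the
# fixed-point iteration in infer_rheogram().

#' Average shear rate from the midline velocity
#'
#' Defined as the maximum midline velocity divided by the channel
#' half-width (7.5 um for the 15 um experimental channel).
#'
#' @param umax_um_s Maximum midline velocity in um/s (>= 0). Vectorised.
#' @param half_width_um Channel half-width in um (default 7.5).
#' @return Average shear rate in 1/s.
#' @export
#' @examples
#' average_shear_rate(750)  # 100 /s
average_shear_rate <- function(umax_um_s, half_width_um = 7.5) {
  if (half_width_um <= 0) stop("half-width must be positive", call. = FALSE)
  if (any(umax_um_s < 0)) stop("velocities must be >= 0", call. = FALSE)
  umax_um_s / half_width_um
}

#' Volumetric flow rate from the maximum midline velocity
#'
#' Q = f u_max h w, where f is the ratio of mean to maximum velocity of the
#' fully developed laminar profile. For a square duct f is about 0.477.
#'
#' @param umax_m_s Maximum midline velocity in m/s. Vectorised.
#' @param geometry [channel_geometry()] of the channel.
#' @param profile_factor Mean/max velocity ratio in (0, 1]; default 0.4771,
#'   the square-duct Poiseuille value.
#' @return Flow rate in m^3/s.
#' @export
experimental_flow_from_velocity <- function(umax_m_s, geometry,
                                            profile_factor = 0.4771) {
  if (profile_factor <= 0 || profile_factor > 1)
    stop("profile_factor must lie in (0, 1]", call. = FALSE)
  profile_factor * umax_m_s * geometry$height_m * geometry$width_m
}

#' Total device flow from the experimental-channel flow
#'
#' The bypass and experimental channels share the same pressure drop, so
#' Q2 c2 eta2 = Q3 c3 eta3 and, with eta2 = B eta3,
#' Q_total = Q3 (1 + c3 / (c2 B)).
#'
#' @param q_experimental Experimental-channel flow rate (m^3/s). Vectorised.
#' @param network A [device_network()].
#' @param B Bypass/experimental viscosity ratio eta2/eta3 (> 0). Vectorised.
#' @return Total flow rate (m^3/s).
#' @export
total_flow <- function(q_experimental, network, B = 1) {
  if (any(B <= 0)) stop("viscosity ratio B must be positive", call. = FALSE)
  q_experimental * (1 + network$c3 / (network$c2 * B))
}

#' Experimental-section effective viscosity from an operating point
#'
#' Algebraic inversion of the network pressure/flow relation for eta3 at
#' fixed viscosity-ratio factors A = eta1/eta3 and B = eta2/eta3:
#'
#'   eta3 = (dp / Q) S / (1 + c1 A S),   S = 1/(c2 B) + 1/c3.
#'
#' For a Newtonian fluid (A = B = 1) this is the exact inverse of the
#' forward resistance relation.
#'
#' @param dp_total_pa Total driving pressure drop (Pa, > 0). Vectorised.
#' @param q_total_m3_s Total flow rate (m^3/s, > 0). Vectorised.
#' @param network A [device_network()].
#' @param A,B Viscosity ratio factors (> 0). Vectorised.
#' @return Effective viscosity eta3 in Pa s.
#' @export
effective_viscosity <- function(dp_total_pa, q_total_m3_s, network,
                                A = 1, B = 1) {
  if (any(dp_total_pa <= 0) || any(q_total_m3_s <= 0))
    stop("pressure drop and flow rate must be positive", call. = FALSE)
  if (any(A <= 0) || any(B <= 0))
    stop("viscosity ratio factors must be positive", call. = FALSE)
  S <- 1 / (network$c2 * B) + 1 / network$c3
  if (any(!is.finite(S)) || any(S <= 0))
    stop("degenerate network constants", call. = FALSE)
  (dp_total_pa / q_total_m3_s) * S / (1 + network$c1 * A * S)
}

#' Settings for rheogram inference
#'
#' @param profile_factor Mean/max laminar velocity ratio (square duct
#'   0.4771).
#' @param velocity_rule How sectional shear rates are computed for the
#'   viscosity-ratio factors. `"continuity"` (default) allocates sectional
#'   mean velocities from flow continuity: the inlet resistor carries the
#'   total flow and the branches split by conductance. `"area_proportional"`
#'   sets sectional velocities proportional to cross-sectional area, the
#'   linearisation used in the original device analysis; it is retained as
#'   an option but conflicts with mass conservation, and a message is
#'   emitted when it is selected.
#' @param tol Relative fixed-point tolerance on eta3 (default 1e-8).
#' @param max_iter Maximum fixed-point iterations (default 100).
#' @param damping Damping factor in (0, 1] applied to the A/B update when
#'   oscillation is detected (default 0.5).
#' @param steady_fraction Fraction of each pressure step, counted from its
#'   end, whose video captures are used (default 0.5): the oxygen tension
#'   and flow must reach steady state before velocities are read.
#' @return A list of class `viscometry_settings`.
#' @export
viscometry_settings <- function(profile_factor = 0.4771,
                                velocity_rule = c("continuity",
                                                  "area_proportional"),
                                tol = 1e-8, max_iter = 100L, damping = 0.5,
                                steady_fraction = 0.5) {
  velocity_rule <- match.arg(velocity_rule)
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1,
            steady_fraction > 0, steady_fraction <= 1)
  if (profile_factor <= 0 || profile_factor > 1)
    stop("profile_factor must lie in (0, 1]", call. = FALSE)
  structure(list(profile_factor = profile_factor,
                 velocity_rule = velocity_rule, tol = tol,
                 max_iter = as.integer(max_iter), damping = damping,
                 steady_fraction = steady_fraction),
            class = "viscometry_settings")
}

# Sectional average shear rates (1/s) for given flows.
# q_total, q_exp in m^3/s; returns list(g1, g2, g3).
section_shear_rates <- function(q_total, q_exp, network, profile_factor,
                                velocity_rule) {
  geo <- function(r) r$geometry
  g_of <- function(q, g) {
    # umax = Q / (f h w); gamma = umax / (h/2)
    (q / (profile_factor * g$height_m * g$width_m)) / (g$height_m / 2)
  }
  g1g <- geo(network$inlet_resistor)
  g2g <- geo(network$bypass)
  g3g <- geo(network$experimental)
  if (is.null(g1g) || is.null(g2g) || is.null(g3g))
    stop("sectional shear rates require resistor geometries; ",
         "networks built from bare constants support only A = B = 1",
         call. = FALSE)
  g3 <- g_of(q_exp, g3g)
  if (velocity_rule == "continuity") {
    q2 <- pmax(q_total - q_exp, .Machine$double.xmin)
    list(g1 = g_of(q_total, g1g), g2 = g_of(q2, g2g), g3 = g3)
  } else {
    # mean velocities proportional to cross-sectional area
    a1 <- g1g$height_m * g1g$width_m
    a2 <- g2g$height_m * g2g$width_m
    a3 <- g3g$height_m * g3g$width_m
    u3max <- q_exp / (profile_factor * a3)
    list(g1 = (u3max * a1 / a3) / (g1g$height_m / 2),
         g2 = (u3max * a2 / a3) / (g2g$height_m / 2),
         g3 = g3)
  }
}

# Average replicates within each (po2, pressure) step after steady-state
# windowing. Returns a data.frame of step summaries.
summarise_steps <- function(trace, steady_fraction) {
  key <- interaction(trace$po2_mmhg, trace$pressure_pa, drop = TRUE)
  parts <- split(trace, key)
  out <- lapply(parts, function(d) {
    tspan <- range(d$time_s)
    if (diff(tspan) > 0) {
      cut <- tspan[1] + (1 - steady_fraction) * diff(tspan)
      keep <- d$time_s >= cut
      if (any(keep)) d <- d[keep, , drop = FALSE]
    }
    data.frame(po2_mmhg = d$po2_mmhg[1], pressure_pa = d$pressure_pa[1],
               umax_um_s = mean(d$umax_um_s),
               sd_um_s = if (nrow(d) > 1) stats::sd(d$umax_um_s) else 0,
               n_rep = nrow(d))
  })
  out <- do.call(rbind, out)
  out[order(out$po2_mmhg, out$pressure_pa), , drop = FALSE]
}

#' Infer effective-viscosity rheograms from a velocity trace
#'
#' For each oxygen tension in the trace, inverts the pressure-step velocity
#' measurements through the device resistor network to obtain effective
#' viscosity versus average shear rate. Because the viscosity-ratio factors
#' A and B depend on the flow behavior index n of the curve being
#' estimated, the inversion is a fixed point: starting from A = B = 1
#' (Newtonian), eta3 is computed at every step, a provisional power law is
#' fitted across the curve, A and B are refreshed from the sectional
#' shear-rate ratios raised to (n - 1), and the cycle repeats until eta3
#' stabilises.
#'
#' @param trace A trace data frame with columns `time_s`, `pressure_pa`,
#'   `po2_mmhg`, `umax_um_s`, `replicate` (see [read_trace()] or
#'   [generate_trace()]).
#' @param network A [device_network()] whose resistors carry geometries.
#' @param settings A [viscometry_settings()].
#' @return A data frame of class `rheogram` with columns `po2_mmhg`,
#'   `shear_rate_per_s`, `viscosity_pa_s`, `shear_stress_pa`, `sd_pa_s`,
#'   ordered by oxygen tension then shear rate, with per-tension
#'   convergence diagnostics in `attr(, "diagnostics")`.
#' @export
infer_rheogram <- function(trace, network,
                           settings = viscometry_settings()) {
  stopifnot(inherits(settings, "viscometry_settings"))
  required <- c("time_s", "pressure_pa", "po2_mmhg", "umax_um_s")
  miss <- setdiff(required, names(trace))
  if (length(miss))
    stop("trace is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(trace$pressure_pa <= 0))
    stop("driving pressures must be positive", call. = FALSE)
  if (any(trace$umax_um_s < 0))
    stop("velocities must be >= 0", call. = FALSE)
  if (all(trace$umax_um_s == 0))
    stop("all velocities are zero; nothing to invert", call. = FALSE)
  if (settings$velocity_rule == "area_proportional")
    message("velocity_rule = 'area_proportional': sectional velocities set ",
            "proportional to cross-sectional area; this linearisation is ",
            "not mass-conserving across the branch point")

  steps <- summarise_steps(trace, settings$steady_fraction)
  g3geo <- network$experimental$geometry
  half_width_um <- g3geo$height_m / 2 * 1e6

  per_po2 <- split(steps, steps$po2_mmhg)
  rows <- list()
  diags <- list()
  for (nm in names(per_po2)) {
    d <- per_po2[[nm]]
    if (nrow(d) < 3)
      stop("oxygen tension ", nm, " has fewer than 3 pressure steps; ",
           "the power-law fit needs at least 3 points", call. = FALSE)
    if (any(d$umax_um_s <= 0))
      stop("oxygen tension ", nm, " has non-positive step-mean velocities",
           call. = FALSE)

    dp <- d$pressure_pa
    umax_m_s <- d$umax_um_s * 1e-6
    g3 <- average_shear_rate(d$umax_um_s, half_width_um)
    q_exp <- experimental_flow_from_velocity(umax_m_s, g3geo,
                                             settings$profile_factor)

    A <- rep(1, nrow(d))
    B <- rep(1, nrow(d))
    eta3 <- NULL
    converged <- FALSE
    n_prov <- 1
    prev_delta <- Inf
    step_len <- 1
    for (it in seq_len(settings$max_iter)) {
      q_tot <- total_flow(q_exp, network, B)
      eta_new <- effective_viscosity(dp, q_tot, network, A, B)
      delta <- if (is.null(eta3)) Inf else max(abs(eta_new - eta3) / eta3)
      eta3 <- eta_new
      if (delta < settings$tol) { converged <- TRUE; break }
      fit <- suppressWarnings(fit_power_law(g3, eta3 * g3))
      n_prov <- fit$n
      sg <- section_shear_rates(q_tot, q_exp, network,
                                settings$profile_factor,
                                settings$velocity_rule)
      A_new <- (sg$g1 / sg$g3)^(n_prov - 1)
      B_new <- (sg$g2 / sg$g3)^(n_prov - 1)
      # damp the ratio-factor update if the error stopped contracting
      if (is.finite(delta) && delta > prev_delta)
        step_len <- step_len * settings$damping
      A <- A + step_len * (A_new - A)
      B <- B + step_len * (B_new - B)
      prev_delta <- delta
    }
    if (!converged) {
      cond <- structure(
        class = c("oxyrheo_convergence_error", "error", "condition"),
        list(message = paste0("rheogram inversion did not converge at ",
                              nm, " mm Hg (last relative change ",
                              signif(prev_delta, 3), ")"),
             call = sys.call(-1), eta3 = eta3, po2_mmhg = as.numeric(nm)))
      stop(cond)
    }
    # first-order propagation of replicate scatter: at fixed A and B,
    # eta3 is inversely proportional to the measured velocity
    rel_sd <- ifelse(d$umax_um_s > 0, d$sd_um_s / d$umax_um_s, 0)
    ord <- order(g3)
    rows[[nm]] <- data.frame(po2_mmhg = d$po2_mmhg[ord],
                             shear_rate_per_s = g3[ord],
                             viscosity_pa_s = eta3[ord],
                             shear_stress_pa = (eta3 * g3)[ord],
                             sd_pa_s = (eta3 * rel_sd)[ord])
    diags[[nm]] <- list(iterations = it, converged = TRUE,
                        provisional_n = n_prov,
                        A = A[ord], B = B[ord])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, diagnostics = diags, settings = settings,
            class = c("rheogram", "data.frame"))
}
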