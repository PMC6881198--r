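# One-dimensional multilayer diffusion model of oxygen transport through
# the vertical device stack (glass | blood | PDMS membrane | hydration |
# PDMS membrane | gas), plus the two-point luminescence calibration for
# the Ru(bpy)3 oxygen-sensitive dye.
#
# Oxygen tension is carried in mm Hg throughout; with pure Fickian
# diffusion and no solubility partitioning between layers the equations
# are linear, so the unit is just a label.

#' Diffusion layer
#'
#' @param name Layer label.
#' @param thickness_um Layer thickness in um (> 0).
#' @param d_cm2_s Diffusion coefficient in cm^2/s (>= 0); PDMS is
#'   3.3e-5 cm^2/s, water 4e-5 cm^2/s.
#' @param material `"pdms"`, `"water"`, or `"glass"`. Glass is not a layer
#'   interior: the slide is represented by the stack's no-flux bottom
#'   boundary.
#' @return An object of class `diffusion_layer`.
#' @export
diffusion_layer <- function(name, thickness_um, d_cm2_s,
                            material = c("water", "pdms", "glass")) {
  material <- match.arg(material)
  if (material == "glass")
    stop("glass is modeled as the no-flux bottom boundary, not a layer",
         call. = FALSE)
  if (thickness_um <= 0) stop("thickness must be positive", call. = FALSE)
  if (d_cm2_s < 0) stop("diffusion coefficient must be >= 0", call. = FALSE)
  structure(list(name = name, thickness_m = thickness_um * 1e-6,
                 d_m2_s = d_cm2_s * 1e-4, material = material),
            class = "diffusion_layer")
}

#' Vertical diffusion layer stack
#'
#' Ordered bottom to top. The bottom boundary is no-flux (the glass
#' slide); the top boundary is held at the gas-reservoir oxygen tension
#' (Dirichlet).
#'
#' @param layers List of [diffusion_layer()] objects, bottom first.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "diffusion_layer")))
  structure(list(layers = layers,
                 total_thickness_m = sum(vapply(layers, `[[`, 0,
                                                "thickness_m"))),
            class = "layer_stack")
}

#' Default device layer stack
#'
#' Bottom to top: 15 um blood channel (water diffusivity), 100 um PDMS
#' membrane, 100 um hydration channel (water), 100 um PDMS membrane; the
#' gas channel above the top membrane sets the Dirichlet boundary.
#'
#' @return A [layer_stack()].
#' @export
default_layer_stack <- function() {
  layer_stack(list(
    diffusion_layer("blood", 15, 4e-5, "water"),
    diffusion_layer("membrane_lower", 100, 3.3e-5, "pdms"),
    diffusion_layer("hydration", 100, 4e-5, "water"),
    diffusion_layer("membrane_upper", 100, 3.3e-5, "pdms")
  ))
}

#' Gas-reservoir switching protocol
#'
#' Piecewise-constant schedule of the gas-channel oxygen tension. The
#' default device protocol cycles between 160 mm Hg (ambient) and
#' 0 mm Hg (anoxic).
#'
#' @param time_s Strictly increasing switch times (s), starting at 0.
#' @param po2_mmhg Gas tensions (mm Hg) applied from each switch time,
#'   each in \[0, 160\].
#' @return A data frame of class `gas_protocol`.
#' @export
#' @examples
#' gas_protocol(c(0, 120), c(160, 0))  # hold ambient, then switch to anoxic
gas_protocol <- function(time_s, po2_mmhg) {
  if (length(time_s) != length(po2_mmhg) || length(time_s) < 1)
    stop("time and tension vectors must have equal positive length",
         call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("switch times must be strictly increasing", call. = FALSE)
  if (any(po2_mmhg < 0 | po2_mmhg > 160))
    stop("gas tensions must lie in [0, 160] mm Hg", call. = FALSE)
  structure(data.frame(time_s = time_s, po2_mmhg = po2_mmhg),
            class = c("gas_protocol", "data.frame"))
}

# Piecewise node diffusivities for a uniform grid over the stack.
# Returns list(z_m, d_node) with N = round(L/dz) + 1 nodes.
stack_grid <- function(stack, dz_m) {
  L <- stack$total_thickness_m
  n <- round(L / dz_m)
  if (abs(n * dz_m - L) / L > 1e-9)
    stop("grid spacing must divide the total stack thickness",
         call. = FALSE)
  z <- seq(0, L, length.out = n + 1)
  bounds <- cumsum(vapply(stack$layers, `[[`, 0, "thickness_m"))
  d_of <- function(zz) {
    i <- findInterval(zz, c(0, bounds), rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(stack$layers))
    vapply(stack$layers[i], `[[`, 0, "d_m2_s")
  }
  # diffusivity sampled at cell midpoints between nodes for interface fluxes
  list(z_m = z, d_mid = d_of((z[-1] + z[-length(z)]) / 2))
}

# Check that every layer is resolved by at least min_nodes grid cells.
check_resolution <- function(stack, dz_m, min_nodes = 5) {
  th <- vapply(stack$layers, `[[`, 0, "thickness_m")
  if (any(th / dz_m < min_nodes - 1e-9))
    stop("grid spacing does not resolve the thinnest layer with at least ",
         min_nodes, " nodes", call. = FALSE)
  invisible(TRUE)
}

#' Simulate oxygen transport through the layer stack
#'
#' Solves the one-dimensional diffusion equation
#' dc/dt = d/dz (D(z) dc/dz) on the vertical stack with a no-flux bottom
#' (glass slide) and the top held at the gas-protocol tension, using a
#' conservative finite-volume discretisation (interface diffusivities
#' sampled between nodes; layer boundaries fall on grid nodes, so each
#' inter-node cell lies in a single layer) and backward-Euler time
#' stepping by default. An explicit
#' scheme is available for cross-validation; its stability condition
#' dt <= dz^2 / (4 max D) (the boundary nodes are half cells) is checked
#' before integration.
#'
#' @param stack A [layer_stack()].
#' @param protocol A [gas_protocol()].
#' @param t_end_s End of the simulated span (s).
#' @param dz_um Grid spacing (um, default 1); must divide the stack
#'   thickness and resolve the thinnest layer with >= 5 nodes.
#' @param dt_s Time step (s, default 0.05).
#' @param initial_mmhg Initial uniform tension (default 160).
#' @param scheme `"implicit"` (default, unconditionally stable) or
#'   `"explicit"`.
#' @param conserving If `TRUE`, replace the Dirichlet top with a no-flux
#'   boundary (sealed stack). Used as a solver self-test: the integrated
#'   concentration is then conserved exactly by the finite-volume scheme.
#' @return List of class `oxygen_simulation`: `time_s`, `z_um`, `conc`
#'   (matrix, rows = times, cols = nodes, mm Hg), plus grid metadata.
#' @export
simulate_gas_switch <- function(stack, protocol, t_end_s, dz_um = 1,
                                dt_s = 0.05, initial_mmhg = 160,
                                scheme = c("implicit", "explicit"),
                                conserving = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(stack, "layer_stack"), inherits(protocol, "gas_protocol"))
  dz <- dz_um * 1e-6
  check_resolution(stack, dz)
  gr <- stack_grid(stack, dz)
  nz <- length(gr$z_m)
  d_mid <- gr$d_mid            # length nz - 1, interface diffusivities
  # boundary nodes are half cells, which doubles their rate constant
  if (scheme == "explicit" && dt_s > dz^2 / (4 * max(d_mid)))
    stop("explicit scheme unstable: need dt <= dz^2 / (4 max D) = ",
         signif(dz^2 / (4 * max(d_mid)), 3), " s", call. = FALSE)

  times <- seq(0, t_end_s, by = dt_s)
  nt <- length(times)
  boundary_at <- function(t) {
    i <- findInterval(t, protocol$time_s)
    if (i < 1) protocol$po2_mmhg[1] else protocol$po2_mmhg[i]
  }

  # finite-volume update: dc_j/dt = (F_{j+1/2} - F_{j-1/2}) / w_j with
  # face fluxes F_{j+1/2} = D_{j+1/2} (c_{j+1} - c_j) / dz, F_{1/2} = 0
  # (no-flux glass), and half-width cells at the boundary nodes so the
  # walls sit exactly on the outermost nodes.
  w <- rep(dz, nz)
  w[1] <- dz / 2
  w[nz] <- dz / 2
  flux_coef <- d_mid / dz       # per face, length nz - 1
  build_A <- function(n_unknown) {
    A <- matrix(0, n_unknown, n_unknown)
    for (j in seq_len(n_unknown)) {
      if (j > 1) {
        A[j, j - 1] <- A[j, j - 1] + flux_coef[j - 1] / w[j]
        A[j, j] <- A[j, j] - flux_coef[j - 1] / w[j]
      }
      if (j < nz) {
        A[j, j] <- A[j, j] - flux_coef[j] / w[j]
        if (j + 1 <= n_unknown)
          A[j, j + 1] <- A[j, j + 1] + flux_coef[j] / w[j]
      }
    }
    A
  }
  if (conserving) {
    n_unknown <- nz
    A <- build_A(nz)
    forcing <- function(g) numeric(nz)
  } else {
    n_unknown <- nz - 1
    A <- build_A(n_unknown)
    forcing <- function(g) {
      f <- numeric(n_unknown)
      f[n_unknown] <- flux_coef[n_unknown] / w[n_unknown] * g
      f
    }
  }

  conc <- matrix(NA_real_, nt, nz)
  c_now <- rep(initial_mmhg, n_unknown)
  g0 <- boundary_at(0)
  conc[1, ] <- c(rep(initial_mmhg, n_unknown), if (!conserving) g0)

  if (scheme == "implicit") {
    M <- solve(diag(n_unknown) - dt_s * A)
    for (k in 2:nt) {
      g <- boundary_at(times[k])
      c_now <- as.vector(M %*% (c_now + dt_s * forcing(g)))
      conc[k, ] <- c(c_now, if (!conserving) g)
    }
  } else {
    for (k in 2:nt) {
      g <- boundary_at(times[k - 1])
      c_now <- c_now + dt_s * (as.vector(A %*% c_now) + forcing(g))
      conc[k, ] <- c(c_now, if (!conserving) boundary_at(times[k]))
    }
  }

  structure(list(time_s = times, z_um = gr$z_m * 1e6, conc = conc,
                 dz_um = dz_um, dt_s = dt_s, scheme = scheme,
                 conserving = conserving, protocol = protocol),
            class = "oxygen_simulation")
}

#' Oxygen tension time series at a probe depth
#'
#' @param sim An `oxygen_simulation`.
#' @param probe_z_um Probe height above the glass slide (um); default 7.5,
#'   the mid-height of the blood channel.
#' @return Data frame `time_s`, `po2_mmhg` (linear interpolation in z).
#' @export
probe_series <- function(sim, probe_z_um = 7.5) {
  if (probe_z_um < min(sim$z_um) || probe_z_um > max(sim$z_um))
    stop("probe lies outside the stack", call. = FALSE)
  i <- findInterval(probe_z_um, sim$z_um, rightmost.closed = TRUE)
  z0 <- sim$z_um[i]
  if (i == length(sim$z_um)) { v <- sim$conc[, i] } else {
    w <- (probe_z_um - z0) / (sim$z_um[i + 1] - z0)
    v <- (1 - w) * sim$conc[, i] + w * sim$conc[, i + 1]
  }
  data.frame(time_s = sim$time_s, po2_mmhg = v)
}

#' Time for the blood channel to reach anoxia
#'
#' First time after the (last downward) gas switch at which the
#' blood-channel probe tension falls below the threshold, located by
#' linear interpolation between time steps.
#'
#' @param sim An `oxygen_simulation`.
#' @param probe_z_um Probe height (um); default 7.5 (mid blood channel).
#' @param threshold_mmhg Anoxia threshold (mm Hg, > 0); default 2
#'   (1.25% of ambient), the operational meaning of "reached 0 mm Hg".
#' @param after_s Count time from this instant (default: the last switch
#'   event in the protocol).
#' @return Seconds from `after_s` to the crossing, or `NA` with a
#'   `"not_reached"` attribute if the simulated span ends first.
#' @export
time_to_anoxia <- function(sim, probe_z_um = 7.5, threshold_mmhg = 2,
                           after_s = NULL) {
  if (threshold_mmhg <= 0) stop("threshold must be positive", call. = FALSE)
  if (is.null(after_s)) after_s <- max(sim$protocol$time_s)
  ps <- probe_series(sim, probe_z_um)
  ps <- ps[ps$time_s >= after_s, , drop = FALSE]
  if (threshold_mmhg >= ps$po2_mmhg[1]) return(0)
  below <- which(ps$po2_mmhg < threshold_mmhg)
  if (!length(below))
    return(structure(NA_real_, not_reached = TRUE))
  i <- below[1]
  t0 <- ps$time_s[i - 1]; t1 <- ps$time_s[i]
  c0 <- ps$po2_mmhg[i - 1]; c1 <- ps$po2_mmhg[i]
  t_cross <- t0 + (c0 - threshold_mmhg) / (c0 - c1) * (t1 - t0)
  t_cross - after_s
}

#' Two-point Stern-Volmer calibration of the oxygen-sensitive dye
#'
#' Oxygen quenches Ru(bpy)3 luminescence following the Stern-Volmer
#' relation I0 / I = 1 + Ksv pO2. Calibrating with intensities at 0 and
#' 160 mm Hg gives Ksv = (I0/I160 - 1) / 160 and the inverse map
#' pO2(I) = (I0/I - 1) / Ksv.
#'
#' @param intensity_0 Luminescence intensity at 0 mm Hg (unquenched).
#' @param intensity_160 Intensity at 160 mm Hg; must satisfy
#'   `intensity_0 > intensity_160 > 0`.
#' @return List of class `sv_calibration`: `k_sv_per_mmhg` and the
#'   function `intensity_to_po2(intensity)`. Intensities above the
#'   unquenched calibration intensity map to 0 mm Hg with a warning.
#' @export
#' @examples
#' cal <- stern_volmer_calibrate(1000, 400)
#' cal$intensity_to_po2(500)  # 106.67 mm Hg
stern_volmer_calibrate <- function(intensity_0, intensity_160) {
  if (!(intensity_0 > intensity_160 && intensity_160 > 0))
    stop("calibration requires I0 > I160 > 0 (oxygen quenches the dye)",
         call. = FALSE)
  k_sv <- (intensity_0 / intensity_160 - 1) / 160
  to_po2 <- function(intensity) {
    if (any(intensity <= 0))
      stop("intensity must be positive", call. = FALSE)
    high <- intensity >= intensity_0
    if (any(intensity > intensity_0))
      warning("intensity above the unquenched calibration; ",
              "clamping to 0 mm Hg")
    po2 <- (intensity_0 / intensity - 1) / k_sv
    po2[high] <- 0
    po2
  }
  structure(list(k_sv_per_mmhg = k_sv, intensity_0 = intensity_0,
                 intensity_160 = intensity_160,
                 intensity_to_po2 = to_po2),
            class = "sv_calibration")
}

#' Two-point linear intensity calibration
#'
#' Linear interpolation between the 0 and 160 mm Hg calibration
#' intensities. Provided for comparison; [stern_volmer_calibrate()] is the
#' physically motivated default for a collisionally quenched dye.
#'
#' @inheritParams stern_volmer_calibrate
#' @return List with `intensity_to_po2(intensity)`.
#' @export
linear_calibrate <- function(intensity_0, intensity_160) {
  if (!(intensity_0 > intensity_160 && intensity_160 > 0))
    stop("calibration requires I0 > I160 > 0", call. = FALSE)
  to_po2 <- function(intensity) {
    po2 <- (intensity_0 - intensity) / (intensity_0 - intensity_160) * 160
    pmin(pmax(po2, 0), 160)
  }
  list(intensity_to_po2 = to_po2)
}
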