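# Hydraulic model of the branching microfluidic viscometer: channel
# geometries, single-channel resistance formulas, and the series/parallel
# resistor network (inlet resistor in series with bypass || experimental).

#' Channel geometry
#'
#' Describes one rectangular-section microchannel in SI units. The device's
#' experimental and bypass channels are square (15 um x 15 um); the inlet
#' pressure-dissipater region is a wide, shallow rectangular channel.
#'
#' @param height_m Channel height h in metres (the short dimension).
#' @param width_m Channel width w in metres. For `shape = "rectangular"` the
#'   formula requires `h <= w`.
#' @param length_m Channel length L in metres.
#' @param shape `"square"` or `"rectangular"`. Square geometries must have
#'   `h == w` (to relative 1e-9); they use the square-duct resistance
#'   constant, which differs from the rectangular formula evaluated at
#'   `h == w` by about 14%, so the routing is enforced, not inferred.
#' @return An object of class `channel_geometry`.
#' @seealso [resistance_square()], [resistance_rectangular()],
#'   [channel_resistance()]
#' @export
#' @examples
#' channel_geometry(15e-6, 15e-6, 0.02, "square")
channel_geometry <- function(height_m, width_m, length_m,
                             shape = c("square", "rectangular")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(height_m), is.numeric(width_m), is.numeric(length_m))
  if (height_m <= 0 || width_m <= 0 || length_m <= 0)
    stop("channel dimensions must be positive", call. = FALSE)
  if (shape == "square" && abs(height_m - width_m) / height_m >= 1e-9)
    stop("shape = 'square' requires height == width", call. = FALSE)
  if (shape == "rectangular" && height_m > width_m)
    stop("rectangular resistance formula requires h <= w; ",
         "swap height and width", call. = FALSE)
  structure(
    list(height_m = height_m, width_m = width_m, length_m = length_m,
         shape = shape),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %s, h = %.3g um, w = %.3g um, L = %.3g mm\n",
              x$shape, x$height_m * 1e6, x$width_m * 1e6, x$length_m * 1e3))
  invisible(x)
}

#' Hydraulic resistance of a square duct
#'
#' Laminar-flow resistance of a square channel,
#' R = 12 eta L / (0.422 h^4). The 0.422 constant is the square-duct
#' correction to the parallel-plate result.
#'
#' @param geometry A [channel_geometry()] with `shape = "square"`.
#' @param viscosity Dynamic viscosity eta in Pa s (>= 0).
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
#' @examples
#' g <- channel_geometry(15e-6, 15e-6, 0.01, "square")
#' resistance_square(g, 0.004)  # 2.247e16 Pa s/m^3
resistance_square <- function(geometry, viscosity) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (geometry$shape != "square")
    stop("resistance_square() requires a square geometry; got '",
         geometry$shape, "'", call. = FALSE)
  if (viscosity < 0) stop("viscosity must be >= 0", call. = FALSE)
  12 * viscosity * geometry$length_m / (0.422 * geometry$height_m^4)
}

#' Hydraulic resistance of a wide rectangular duct
#'
#' Laminar-flow resistance of a rectangular channel with aspect ratio
#' h <= w: R = 12 eta L / ((1 - 0.63 h/w) h^3 w). This approximation
#' degrades as h -> w; square channels must use [resistance_square()].
#'
#' @param geometry A [channel_geometry()] with `shape = "rectangular"`.
#' @param viscosity Dynamic viscosity eta in Pa s (>= 0).
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
resistance_rectangular <- function(geometry, viscosity) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (geometry$shape != "rectangular")
    stop("resistance_rectangular() requires a rectangular geometry; got '",
         geometry$shape, "'", call. = FALSE)
  if (viscosity < 0) stop("viscosity must be >= 0", call. = FALSE)
  h <- geometry$height_m
  w <- geometry$width_m
  12 * viscosity * geometry$length_m / ((1 - 0.63 * h / w) * h^3 * w)
}

#' Hydraulic resistance of a channel, dispatched on its shape
#'
#' @inheritParams resistance_square
#' @param geometry A [channel_geometry()].
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
channel_resistance <- function(geometry, viscosity) {
  switch(geometry$shape,
         square = resistance_square(geometry, viscosity),
         rectangular = resistance_rectangular(geometry, viscosity))
}

#' Geometric resistance constant of a channel
#'
#' The constant c = R/eta (units 1/m^3) that multiplies the sectional
#' effective viscosity in the network resistance formula.
#'
#' @param geometry A [channel_geometry()].
#' @return c in 1/m^3.
#' @export
geometric_constant <- function(geometry) channel_resistance(geometry, 1)

#' Hydraulic resistor (channel + role in the network)
#'
#' A resistor is either built from a geometry (its constant c is computed
#' and cached) or from an explicitly supplied constant when the physical
#' geometry of a device region is not known.
#'
#' @param role One of `"inlet_resistor"`, `"bypass"`, `"experimental"`.
#' @param geometry A [channel_geometry()], or `NULL` if `c_per_m3` is given.
#' @param c_per_m3 Geometric constant in 1/m^3; computed from `geometry`
#'   when omitted.
#' @return An object of class `hydraulic_resistor`.
#' @export
hydraulic_resistor <- function(role = c("inlet_resistor", "bypass",
                                        "experimental"),
                               geometry = NULL, c_per_m3 = NULL) {
  role <- match.arg(role)
  if (is.null(c_per_m3)) {
    if (is.null(geometry))
      stop("supply either a geometry or an explicit c_per_m3", call. = FALSE)
    c_per_m3 <- geometric_constant(geometry)
  }
  if (!is.numeric(c_per_m3) || c_per_m3 <= 0)
    stop("geometric constant must be positive", call. = FALSE)
  structure(list(role = role, geometry = geometry, c_per_m3 = c_per_m3),
            class = "hydraulic_resistor")
}

#' Device resistor network
#'
#' Fixed topology: the inlet resistor in series with the parallel pair of
#' bypass and experimental channels, valid in the creeping-flow regime
#' (Re < 1).
#'
#' @param inlet_resistor,bypass,experimental [hydraulic_resistor()] objects
#'   with matching roles.
#' @return An object of class `device_network` with cached constants
#'   `c1` (inlet), `c2` (bypass), `c3` (experimental), all in 1/m^3.
#' @export
device_network <- function(inlet_resistor, bypass, experimental) {
  rs <- list(inlet_resistor, bypass, experimental)
  roles <- vapply(rs, `[[`, "", "role")
  if (!identical(roles, c("inlet_resistor", "bypass", "experimental")))
    stop("resistors must be supplied in order inlet_resistor, bypass, ",
         "experimental with matching roles", call. = FALSE)
  structure(
    list(inlet_resistor = inlet_resistor, bypass = bypass,
         experimental = experimental,
         c1 = inlet_resistor$c_per_m3, c2 = bypass$c_per_m3,
         c3 = experimental$c_per_m3),
    class = "device_network"
  )
}

#' @export
print.device_network <- function(x, ...) {
  cat(sprintf(paste0("<device_network> inlet in series with ",
                     "(bypass || experimental)\n",
                     "  c1 = %.4g, c2 = %.4g, c3 = %.4g 1/m^3\n"),
              x$c1, x$c2, x$c3))
  invisible(x)
}

#' Default device network
#'
#' The experimental and bypass channels are 15 um x 15 um square ducts.
#' Their lengths and the geometry of the inlet pressure-dissipater region
#' are not published for the physical device, so the defaults here are
#' illustrative values of realistic magnitude (20 mm square branches and a
#' 40 mm x 100 um x 15 um rectangular inlet resistor); all analyses accept
#' explicit constants instead.
#'
#' @return A [device_network()].
#' @export
default_device_network <- function() {
  device_network(
    hydraulic_resistor("inlet_resistor",
                       channel_geometry(15e-6, 100e-6, 0.04, "rectangular")),
    hydraulic_resistor("bypass",
                       channel_geometry(15e-6, 15e-6, 0.02, "square")),
    hydraulic_resistor("experimental",
                       channel_geometry(15e-6, 15e-6, 0.02, "square"))
  )
}

#' Total hydraulic resistance of the device network
#'
#' R_hyd = c1 eta1 + 1 / (1/(c2 eta2) + 1/(c3 eta3)): the inlet resistor in
#' series with the parallel bypass/experimental pair, each section carrying
#' its own effective viscosity.
#'
#' @param network A [device_network()].
#' @param eta1,eta2,eta3 Sectional effective viscosities (Pa s, > 0) of the
#'   inlet resistor, bypass, and experimental channel. Vectorised.
#' @return Total resistance in Pa s / m^3.
#' @export
network_resistance <- function(network, eta1, eta2, eta3) {
  if (any(eta1 <= 0) || any(eta2 <= 0) || any(eta3 <= 0))
    stop("sectional viscosities must be positive", call. = FALSE)
  network$c1 * eta1 +
    1 / (1 / (network$c2 * eta2) + 1 / (network$c3 * eta3))
}

#' Fluid state for Reynolds-number evaluation
#'
#' @param density_kg_m3 Fluid density rho (kg/m^3).
#' @param viscosity_pa_s Dynamic viscosity mu (Pa s).
#' @param velocity_m_s Mean (or characteristic) velocity u (m/s, >= 0).
#' @return An object of class `fluid_state`.
#' @export
fluid_state <- function(density_kg_m3, viscosity_pa_s, velocity_m_s) {
  if (density_kg_m3 <= 0 || viscosity_pa_s <= 0 || velocity_m_s < 0)
    stop("require rho > 0, mu > 0, u >= 0", call. = FALSE)
  structure(list(density_kg_m3 = density_kg_m3,
                 viscosity_pa_s = viscosity_pa_s,
                 velocity_m_s = velocity_m_s),
            class = "fluid_state")
}

#' Channel Reynolds number
#'
#' Re = rho u L / mu with L the hydraulic diameter. For whole blood in the
#' 15 um channels at the highest observed velocities Re is about 0.014,
#' which justifies the creeping-flow resistor-network model.
#'
#' @param fluid A [fluid_state()].
#' @param hydraulic_diameter_m Hydraulic diameter L in metres.
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' reynolds_number(fluid_state(1060, 0.004, 3500e-6), 15e-6)
reynolds_number <- function(fluid, hydraulic_diameter_m) {
  stopifnot(inherits(fluid, "fluid_state"))
  if (hydraulic_diameter_m <= 0)
    stop("hydraulic diameter must be positive", call. = FALSE)
  fluid$density_kg_m3 * fluid$velocity_m_s * hydraulic_diameter_m /
    fluid$viscosity_pa_s
}
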