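# Power-law characterisation of rheograms: flow behavior index n,
# consistency index K, goodness of fit, and the fractional velocity
# change metric used to compare oxygenated and deoxygenated flow.

#' Fit a power law to shear stress vs shear rate
#'
#' Ordinary least squares of log10(tau) on log10(gamma-dot). The slope is
#' the flow behavior index n (n = 1 Newtonian, n < 1 shear-thinning), the
#' intercept is log10 of the consistency index K (Pa s^n), and the
#' goodness of fit is the R^2 of the log-log linear regression.
#'
#' @param shear_rate_per_s Average shear rates (1/s, > 0), length >= 3.
#' @param shear_stress_pa Shear stresses (Pa, > 0), same length.
#' @param weights Optional non-negative regression weights (e.g. inverse
#'   variances from replicate SD). Default `NULL`: unweighted.
#' @param po2_mmhg Optional oxygen-tension label carried into the result.
#' @return An object of class `power_law_fit`: list with elements `n`,
#'   `K_pa_sn`, `r2`, `n_points`, `po2_mmhg`.
#' @export
#' @examples
#' fit_power_law(c(1, 10, 100), 2 * c(1, 10, 100)^0.8)  # n = 0.8, K = 2
fit_power_law <- function(shear_rate_per_s, shear_stress_pa, weights = NULL,
                          po2_mmhg = NA_real_) {
  if (length(shear_rate_per_s) != length(shear_stress_pa))
    stop("shear rate and stress vectors must have equal length",
         call. = FALSE)
  if (length(shear_rate_per_s) < 3)
    stop("power-law fit needs at least 3 points", call. = FALSE)
  if (any(shear_rate_per_s <= 0) || any(shear_stress_pa <= 0))
    stop("power-law fit requires positive shear rates and stresses",
         call. = FALSE)
  x <- log10(shear_rate_per_s)
  y <- log10(shear_stress_pa)
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  co <- stats::coef(fit)
  # suppress the lm "essentially perfect fit" note on noiseless data
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(n = unname(co[2]), K_pa_sn = unname(10^co[1]), r2 = r2,
                 n_points = length(x), po2_mmhg = po2_mmhg),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  lab <- if (is.na(x$po2_mmhg)) "" else sprintf(" @ %g mm Hg", x$po2_mmhg)
  cat(sprintf("<power_law_fit>%s n = %.3f, K = %.4g Pa s^n, R^2 = %.4f (%d points)\n",
              lab, x$n, x$K_pa_sn, x$r2, x$n_points))
  invisible(x)
}

#' Fit power laws to every oxygen tension of a rheogram
#'
#' @param rheogram A `rheogram` from [infer_rheogram()] (or any data frame
#'   with columns `po2_mmhg`, `shear_rate_per_s`, `shear_stress_pa`).
#' @param weighted Use inverse-variance weights from the rheogram's
#'   `sd_pa_s` column where available (default `FALSE`).
#' @return A data frame with one row per oxygen tension: `po2_mmhg`, `n`,
#'   `K_pa_sn`, `r2`, `n_points`.
#' @export
fit_rheogram <- function(rheogram, weighted = FALSE) {
  parts <- split(as.data.frame(rheogram), rheogram$po2_mmhg)
  rows <- lapply(parts, function(d) {
    w <- NULL
    if (weighted && !is.null(d$sd_pa_s) && all(d$sd_pa_s > 0))
      w <- 1 / d$sd_pa_s^2
    f <- fit_power_law(d$shear_rate_per_s, d$shear_stress_pa, weights = w,
                       po2_mmhg = d$po2_mmhg[1])
    data.frame(po2_mmhg = d$po2_mmhg[1], n = f$n, K_pa_sn = f$K_pa_sn,
               r2 = f$r2, n_points = f$n_points)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$po2_mmhg, decreasing = TRUE), , drop = FALSE]
}

#' Shear stress from effective viscosity and shear rate
#'
#' tau = eta gamma-dot, the link between the viscosity rheogram and the
#' stress/rate curve the power law is fitted to.
#'
#' @param viscosity_pa_s Effective viscosity (Pa s, >= 0). Vectorised.
#' @param shear_rate_per_s Average shear rate (1/s, >= 0). Vectorised.
#' @return Shear stress in Pa.
#' @export
shear_stress <- function(viscosity_pa_s, shear_rate_per_s) {
  if (any(viscosity_pa_s < 0) || any(shear_rate_per_s < 0))
    stop("inputs must be >= 0", call. = FALSE)
  viscosity_pa_s * shear_rate_per_s
}

#' Fractional velocity change between oxygenated and deoxygenated flow
#'
#' (v_ox - v_deox) / v_ox: 0 for oxygen-independent flow (healthy blood),
#' approaching 1 as deoxygenated flow stops (full occlusion).
#'
#' @param v_oxygenated Velocity under oxygenation (> 0). Vectorised.
#' @param v_deoxygenated Velocity under deoxygenation (>= 0). Vectorised.
#' @return Dimensionless fraction.
#' @export
fractional_velocity_change <- function(v_oxygenated, v_deoxygenated) {
  if (any(v_oxygenated <= 0))
    stop("oxygenated velocity must be positive", call. = FALSE)
  if (any(v_deoxygenated < 0))
    stop("deoxygenated velocity must be >= 0", call. = FALSE)
  (v_oxygenated - v_deoxygenated) / v_oxygenated
}
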