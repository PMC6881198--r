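# Synthetic oxygen- and HbS-dependent power-law material law for blood,
# and transfusion mixing by hemoglobin mass balance.
#
# Sickle blood is modeled as a shear-thinning power-law fluid
# tau = K(pO2) gamma^n(pO2) whose flow behavior index anchors are the
# cohort means observed in the device (n = 0.76 at 92 mm Hg, 0.74 at 46,
# 0.87 at 0, constant above 92). Healthy blood (HbS = 0) is oxygen
# independent. Consistency-index multipliers are illustrative: no absolute
# viscosity magnitudes are anchored, only their ordering (viscosity at a
# given shear rate rises as oxygen falls).

#' Blood sample composition
#'
#' @param hct Hematocrit as a volume fraction in (0, 1); all device
#'   experiments modeled here fix 0.25.
#' @param mchc_g_dl Mean corpuscular hemoglobin concentration (g/dL).
#' @param hbs,hba,hbf Hemoglobin S / A / F mass fractions, each in
#'   \[0, 1\], summing (with minor species) to at most 1.
#' @return An object of class `sample_composition`.
#' @export
sample_composition <- function(hct = 0.25, mchc_g_dl = 33,
                               hbs = 0, hba = 1, hbf = 0) {
  if (hct <= 0 || hct >= 1) stop("HCT must lie in (0, 1)", call. = FALSE)
  if (mchc_g_dl <= 0) stop("MCHC must be positive", call. = FALSE)
  fr <- c(hbs, hba, hbf)
  if (any(fr < 0)) stop("hemoglobin fractions must be >= 0", call. = FALSE)
  if (sum(fr) > 1 + 1e-9)
    stop("hemoglobin fractions must sum to at most 1", call. = FALSE)
  structure(list(hct = hct, mchc_g_dl = mchc_g_dl,
                 hbs = hbs, hba = hba, hbf = hbf),
            class = "sample_composition")
}

#' Parameters of the synthetic blood material law
#'
#' @param n_po2_mmhg Oxygen-tension anchor points for the flow behavior
#'   index, descending (default 92, 46, 0 mm Hg).
#' @param n_anchors Sickle-blood flow behavior indices at those anchors
#'   (default 0.76, 0.74, 0.87 - the cohort means; constant above the
#'   highest anchor, piecewise linear in between).
#' @param k_oxy_pa_sn Consistency index at and above the highest anchor
#'   (Pa s^n). Default 0.012, chosen so that oxygenated effective
#'   viscosity at 100 /s is about 4 mPa s for 25% HCT blood; illustrative,
#'   not an anchored magnitude.
#' @param k_multipliers Consistency multipliers at the anchors relative to
#'   `k_oxy_pa_sn` (default 1, 1.35, 1.9), chosen so viscosity at 100 /s
#'   strictly increases with deoxygenation; illustrative.
#' @param healthy_n,healthy_k Oxygen-independent law for HbS = 0 blood.
#'   Default n = 0.76 (the oxygenated sickle value: transfusion restores
#'   the shear-thinning shape) and the oxygenated K.
#' @param noise_cv Multiplicative replicate noise CV (default 0.05).
#' @param sensitivity Mixture nonlinearity exponent s >= 0 (see
#'   [mixture_blood_model()]); default 1 (linear mixing).
#' @param hbs_ref HbS mass fraction of untransfused sickle blood used to
#'   normalise mixtures (default 0.7; compositions at or above it behave
#'   as fully sickle).
#' @return A list of class `blood_model_params`.
#' @export
blood_model_params <- function(n_po2_mmhg = c(92, 46, 0),
                               n_anchors = c(0.76, 0.74, 0.87),
                               k_oxy_pa_sn = 0.012,
                               k_multipliers = c(1, 1.35, 1.9),
                               healthy_n = 0.76, healthy_k = 0.012,
                               noise_cv = 0.05, sensitivity = 1,
                               hbs_ref = 0.7) {
  if (length(n_po2_mmhg) != length(n_anchors) ||
      length(n_po2_mmhg) != length(k_multipliers))
    stop("anchor vectors must have equal length", call. = FALSE)
  if (any(!is.finite(n_anchors)) || any(n_anchors <= 0) ||
      any(n_anchors >= 1.5))
    stop("flow-behavior-index anchors must be finite and in (0, 1.5)",
         call. = FALSE)
  if (any(!is.finite(k_multipliers)) || any(k_multipliers <= 0) ||
      k_oxy_pa_sn <= 0 || healthy_k <= 0)
    stop("consistency anchors must be finite and positive", call. = FALSE)
  if (sensitivity < 0) stop("sensitivity must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  structure(list(n_po2_mmhg = n_po2_mmhg, n_anchors = n_anchors,
                 k_oxy_pa_sn = k_oxy_pa_sn, k_multipliers = k_multipliers,
                 healthy_n = healthy_n, healthy_k = healthy_k,
                 noise_cv = noise_cv, sensitivity = sensitivity,
                 hbs_ref = hbs_ref),
            class = "blood_model_params")
}

# Piecewise-linear interpolator constant beyond the anchor range.
anchor_fun <- function(po2, values) {
  ord <- order(po2)
  x <- po2[ord]; y <- values[ord]
  function(p) stats::approx(x, y, xout = p, rule = 2)$y
}

#' Build the oxygen-dependent material law for a blood sample
#'
#' Untransfused sickle blood (HbS at or above the reference fraction)
#' follows the anchored oxygen-dependent law; healthy blood (HbS = 0) is
#' oxygen independent; intermediate HbS fractions interpolate between the
#' two via [mixture_blood_model()] with the params' sensitivity.
#'
#' @param composition A [sample_composition()].
#' @param params A [blood_model_params()].
#' @return An object of class `blood_model`: functions `n_fun(po2)` and
#'   `k_fun(po2)` plus `noise_cv` and the composition.
#' @export
#' @examples
#' m <- build_blood_model(sample_composition(hbs = 1, hba = 0))
#' m$n_fun(46)  # 0.74
build_blood_model <- function(composition,
                              params = blood_model_params()) {
  stopifnot(inherits(composition, "sample_composition"),
            inherits(params, "blood_model_params"))
  healthy <- structure(
    list(n_fun = function(p) rep(params$healthy_n, length(p)),
         k_fun = function(p) rep(params$healthy_k, length(p)),
         noise_cv = params$noise_cv, composition = composition,
         label = "healthy"),
    class = "blood_model")
  if (composition$hbs == 0) return(healthy)
  n_f <- anchor_fun(params$n_po2_mmhg, params$n_anchors)
  k_f <- anchor_fun(params$n_po2_mmhg,
                    params$k_oxy_pa_sn * params$k_multipliers)
  sickle <- structure(
    list(n_fun = n_f, k_fun = k_f, noise_cv = params$noise_cv,
         composition = composition, label = "sickle"),
    class = "blood_model")
  f <- min(composition$hbs / params$hbs_ref, 1)
  if (f >= 1) return(sickle)
  mixture_blood_model(sickle, healthy, f, params$sensitivity)
}

#' @export
print.blood_model <- function(x, ...) {
  cat(sprintf("<blood_model> %s: n(92/46/0) = %.3f/%.3f/%.3f, CV = %g\n",
              x$label, x$n_fun(92), x$n_fun(46), x$n_fun(0), x$noise_cv))
  invisible(x)
}

#' Mix a sickle and a donor sample by transfusion
#'
#' Both samples are resuspended to the same hematocrit, so mixing volume
#' fraction v of sickle blood with (1 - v) donor blood combines
#' hemoglobin in proportion to v MCHC. The mixture HbS mass fraction is
#' v MCHC_s HbS_s / (v MCHC_s + (1 - v) MCHC_d), and likewise for HbA and
#' HbF; HCT is unchanged.
#'
#' @param sickle,donor [sample_composition()] objects at the same HCT.
#' @param sickle_volume_fraction v in \[0, 1\].
#' @return The mixture [sample_composition()].
#' @export
mix_transfusion <- function(sickle, donor, sickle_volume_fraction) {
  v <- sickle_volume_fraction
  if (v < 0 || v > 1) stop("volume fraction must lie in [0, 1]",
                           call. = FALSE)
  if (abs(sickle$hct - donor$hct) > 1e-9)
    stop("samples must be fixed at the same HCT before mixing",
         call. = FALSE)
  ms <- v * sickle$mchc_g_dl
  md <- (1 - v) * donor$mchc_g_dl
  tot <- ms + md
  sample_composition(
    hct = sickle$hct,
    mchc_g_dl = tot,
    hbs = (ms * sickle$hbs + md * donor$hbs) / tot,
    hba = (ms * sickle$hba + md * donor$hba) / tot,
    hbf = (ms * sickle$hbf + md * donor$hbf) / tot
  )
}

#' Sickle volume fraction achieving a target HbS mass fraction
#'
#' Inverts the transfusion mass balance for the sickle volume fraction v
#' that yields the requested mixture HbS fraction (e.g. the 0, 7.5, 25,
#' 50, 75% testing values, or the 30% clinical transfusion target).
#'
#' @param sickle,donor [sample_composition()] objects at the same HCT.
#' @param target_hbs Target HbS mass fraction in \[0, sickle HbS\].
#' @return v in \[0, 1\].
#' @export
transfusion_volume_fraction <- function(sickle, donor, target_hbs) {
  hbs_at <- function(v) mix_transfusion(sickle, donor, v)$hbs
  if (target_hbs < hbs_at(0) - 1e-12 || target_hbs > hbs_at(1) + 1e-12)
    stop("target HbS fraction is not reachable by mixing these samples",
         call. = FALSE)
  if (target_hbs <= hbs_at(0)) return(0)
  if (target_hbs >= hbs_at(1)) return(1)
  stats::uniroot(function(v) hbs_at(v) - target_hbs, c(0, 1),
                 tol = 1e-12)$root
}

#' Interpolate between sickle and healthy material laws
#'
#' The mixture law weights the sickle endpoint by w = f^s, where f is the
#' HbS mass fraction normalised to the untransfused level and s is a
#' patient-specific sensitivity: s = 1 gives linear mixing; s > 1 means
#' the sample recovers healthy behavior early (already at high HbS);
#' s < 1 means recovery only near full exchange. n mixes linearly and K
#' geometrically (linearly in log K).
#'
#' @param sickle_model,healthy_model `blood_model` objects.
#' @param f Normalised HbS fraction in \[0, 1\].
#' @param sensitivity s >= 0.
#' @return A `blood_model`.
#' @export
mixture_blood_model <- function(sickle_model, healthy_model, f,
                                sensitivity = 1) {
  if (f < 0 || f > 1)
    stop("normalised HbS fraction must lie in [0, 1]", call. = FALSE)
  if (sensitivity < 0) stop("sensitivity must be >= 0", call. = FALSE)
  w <- f^sensitivity
  structure(
    list(
      n_fun = function(p) {
        (1 - w) * healthy_model$n_fun(p) + w * sickle_model$n_fun(p)
      },
      k_fun = function(p) {
        exp((1 - w) * log(healthy_model$k_fun(p)) +
            w * log(sickle_model$k_fun(p)))
      },
      noise_cv = sickle_model$noise_cv,
      composition = sickle_model$composition,
      label = sprintf("mixture(f = %.3g, s = %.3g)", f, sensitivity)
    ),
    class = "blood_model")
}
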