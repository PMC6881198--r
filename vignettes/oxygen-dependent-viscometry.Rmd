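---
title: "Oxygen-dependent microfluidic viscometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen-dependent microfluidic viscometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyrheo)
```

## The measurement problem

Sickle cell blood stiffens as oxygen tension falls: hemoglobin S
polymerises, red cells lose deformability, and the effective viscosity of
whole blood rises — steeply so at low shear rates. A branching
microfluidic device measures this by driving blood through a 15 µm
square "experimental" channel held at a controlled oxygen tension, with
a parallel oxygenated bypass that keeps blood moving even when the
experimental branch occludes, and an upstream resistor region that
dissipates most of the driving pressure. What is observed is the maximum
midline velocity in the experimental channel at a series of driving
pressures; what is wanted is the effective viscosity of the blood in
that channel as a function of the average shear rate, at each oxygen
tension.

`oxyrheo` implements that conversion and everything needed to exercise
it end to end: the hydraulic network model, the fixed-point inversion,
power-law rheology fits, a one-dimensional model of oxygen transport
through the device's layer stack, transfusion mixing arithmetic, cohort
statistics, and a synthetic-data generator that stands in for patient
measurements.

## The hydraulic network model

At the device's operating point the Reynolds number is about 0.014
(`reynolds_number()`), so inertia is negligible and each channel behaves
as a linear hydraulic resistor whose resistance factorises as
R = c·η, with c a purely geometric constant (1/m³) and η the effective
viscosity of the blood inside it. The device is the inlet resistor in
series with the bypass/experimental parallel pair:

R_hyd = c₁η₁ + 1 / (1/(c₂η₂) + 1/(c₃η₃)).

Square channels use R = 12ηL/(0.422h⁴) and wide rectangular channels
R = 12ηL/((1 − 0.63h/w)h³w). The two formulas disagree by ≈14% at
h = w, so the square form is enforced for square geometries rather than
inferred from the aspect ratio.

The published device does not include the geometry of the resistor
region or numeric c₁, c₂, c₃, so `default_device_network()` uses
illustrative values of realistic magnitude (20 mm, 15 µm square branch
channels; a 40 mm × 100 µm × 15 µm inlet resistor). These were chosen
once so that the oxygenated default blood reaches a maximum midline
velocity of ≈3.5 mm/s at the top default pressure step — the top of the
published operating envelope — and are not calibrated to anything else.
Configurations may supply explicit constants instead
(`device$constants` in the config).

## From velocities to a rheogram

For each pressure step the measured midline velocity gives

* the average shear rate γ̇₃ = u_max / (h/2) (half-width 7.5 µm),
* the experimental-channel flow Q₃ = f·u_max·h·w, with f ≈ 0.477 the
  square-duct Poiseuille mean/max velocity ratio,

and the unknown sectional viscosities are reduced to the experimental
one via η₁ = A·η₃, η₂ = B·η₃. For a power-law fluid
(τ = Kγ̇ⁿ) the ratios are exactly the sectional shear-rate ratios raised
to (n − 1). Since n is a property of the curve being estimated, the
inversion iterates:

1. start Newtonian (A = B = 1);
2. compute Q_total = Q₃(1 + c₃/(c₂B)) and
   η₃ = (Δp/Q_total)·S/(1 + c₁AS), S = 1/(c₂B) + 1/c₃, at every step;
3. fit a provisional power law across the curve to get n;
4. refresh A and B from the sectional shear-rate ratios;
5. repeat until the largest relative change in η₃ is below 10⁻⁸
   (default; at most 100 iterations, with the ratio-factor update damped
   by 0.5 whenever the error stops contracting).

Two rules are offered for the sectional shear rates. The default,
`continuity`, allocates flows by mass conservation: the inlet resistor
carries Q_total and the bypass carries Q_total − Q₃, each converted to a
mean velocity by its own cross-section. The alternative,
`area_proportional`, sets sectional velocities proportional to
cross-sectional area — the linearisation used in the original device
analysis. The two conflict (velocities proportional to area do not
conserve volume flux across a branch point), so the mass-conserving rule
is the default and selecting the other one emits a message. On
synthetic data generated under continuity the fixed point recovers a
noiseless power-law fluid's η₃(γ̇) to ≈10⁻⁹ relative, and the converged
solution satisfies the full nonlinear pressure balance to better than
10⁻⁶.

How the ratio factors were generated "between each shear rate step" in
the original analysis is not specified; the global power-law update used
here is a reconstruction, and the per-tension convergence diagnostics
(iterations, final A and B) are attached to every rheogram so the
scheme is auditable.

Replicate velocities (by default 18 captures per step, taken from the
steady-state second half of each step) are averaged before inversion;
their scatter is propagated to the rheogram as a first-order SD — at
fixed A and B, η₃ is inversely proportional to the measured velocity,
so the relative SD carries over directly.

## Power-law fits and derived metrics

`fit_power_law()` regresses log₁₀τ on log₁₀γ̇ by ordinary least squares:
slope = flow behavior index n, intercept = log₁₀K, and the goodness of
fit is the R² of that linear regression — the standard choice in the
fitting space, adopted here because the original figure plots a
goodness-of-fit without defining one. Weighted fits (inverse variance
from replicate SD) are available but off by default. The log base does
not affect n or R². `fractional_velocity_change()` is
(v_ox − v_deox)/v_ox.

## Oxygen transport through the layer stack

The device stack, bottom to top: glass slide (no-flux), 15 µm blood
channel (water diffusivity 4×10⁻⁵ cm²/s), 100 µm PDMS membrane
(3.3×10⁻⁵ cm²/s), 100 µm hydration channel (water), 100 µm PDMS
membrane, and the gas channel, which pins the top boundary at the
reservoir tension (Dirichlet). The three-dimensional transport problem
is reduced to this one-dimensional vertical path — the dominant route —
and solved as ∂c/∂t = ∂/∂z(D(z)∂c/∂z) with a conservative finite-volume
scheme: nodes every 1 µm (layer boundaries fall on nodes; boundary
nodes are half cells so the walls sit exactly on the outermost nodes),
backward-Euler steps of 0.05 s by default. The implicit matrix is
factored once per run, so a 200 s simulation costs a few thousand dense
matrix-vector products at ~300 nodes. An explicit scheme is provided
for cross-validation and refuses to run outside its stability bound
dt ≤ dz²/(4 max D). A sealed-stack mode (both boundaries no-flux)
serves as a solver self-test: the cell-weighted total concentration is
conserved to 10⁻¹⁰ per run.

No solubility partitioning is applied between PDMS and water — the model
is pure Fickian diffusion with piecewise D, mirroring the published
transport model, which specifies only diffusion coefficients. Oxygen
tension is therefore a linear field and mm Hg is just a label. Lateral
in-plane supply from device walls held at ambient is neglected.

"Reached 0 mm Hg" is operationalised as the blood-channel mid-height
probe (z = 7.5 µm) falling below 2 mm Hg (1.25% of ambient),
configurable. With the default stack this happens ≈53 s after a
160 → 0 mm Hg switch, consistent with the observed ≈60 s; given the
3-D → 1-D reduction, agreement within a factor of two is the declared
target, and the solver's own accuracy is checked separately against the
analytic cosine-series solution of a uniform slab (≤0.5% error) and by
grid convergence (<2% change on halving dz).

The Ru(bpy)₃ luminescence calibration is two-point Stern–Volmer:
K_sv = (I₀/I₁₆₀ − 1)/160 and pO₂(I) = (I₀/I − 1)/K_sv. A linear
two-point map is provided for comparison, but collisional quenching is
physically nonlinear in intensity, so Stern–Volmer is the default; which
was used originally is not stated.

## The synthetic blood model

The generator emulates the statistical structure the analysis assumes —
not the microscopic physics of sickling. Blood is a power-law fluid
whose parameters depend on oxygen tension and HbS fraction:

* untransfused sickle blood: n(pO₂) interpolates linearly through the
  anchors (92, 0.76), (46, 0.74), (0, 0.87) — the published cohort
  means — and is constant above 92 mm Hg; K(pO₂) rises as
  K_oxy·(1, 1.35, 1.9) at those anchors. K_oxy = 0.012 Pa·sⁿ makes the
  oxygenated effective viscosity ≈4 mPa·s at 100 /s, a plausible value
  for 25% HCT blood; these magnitudes are illustrative, since no
  absolute viscosities are published in text — recovery tests therefore
  target the curve shape (n), not absolute K.
* healthy blood (HbS = 0): oxygen-independent, with n = 0.76 (no
  healthy index is published; transfusion is described as restoring the
  shear-thinning shape of oxygenated sickle blood) and K = K_oxy.
* mixtures: n mixes linearly and K geometrically between the endpoints
  with sickle weight w = f^s, where f is the HbS fraction normalised to
  the untransfused level (default 0.7) and s a patient-specific
  sensitivity — s > 1 recovers healthy behavior while HbS is still
  high, s < 1 only near full exchange, capturing the patient-to-patient
  differences seen in transfusion response.

Transfusion compositions follow the hemoglobin mass balance: at a
common hematocrit, mixing volume fraction v of sickle blood with MCHC_s
against donor blood with MCHC_d gives mixture HbS fraction
v·MCHC_s·HbS_s/(v·MCHC_s + (1−v)·MCHC_d);
`transfusion_volume_fraction()` inverts this for the 0–75% HbS testing
ladder or the 30% clinical target.

Traces are generated by solving the full nonlinear forward problem at
each pressure step — bracketed root finding on the experimental flow
with every section's viscosity evaluated at its own shear rate — then
adding multiplicative Gaussian noise (CV 5%) across 18 replicates. The
default protocol is 8 log-spaced pressure steps (1–25 kPa) spanning
average shear rates ≈20–500 /s for oxygenated blood, straddling the
100 /s comparison point. Cohorts draw per-patient n anchors from
normal distributions with the published between-subject SDs (0.075,
0.049, 0.056), truncated to (0.3, 1.3). All randomness flows from one
explicit seed, and the generating truth is always returned with the
data.

One simplification matters for interpretation: the forward model
applies the sample's material law *at the trace's oxygen tension* in
all three sections, whereas in the physical device the bypass and inlet
stay oxygenated. The inversion's ratio-factor model makes exactly the
same single-fluid assumption, so the round trip is well-posed; what
passing recovery tests demonstrate is the correctness of the inversion
under the model's own assumptions, not the magnitude of the bias that
assumption carries on real devices (where it is shared by the original
analysis). Likewise the generator does not emulate hematocrit drift,
cell adhesion, occlusion events, or the breakdown of the power law at
0 mm Hg beyond what the fitted R² reveals.

## Cohort statistics

Flow behavior indices across oxygen tensions form a complete
patient × condition table. `friedman_test()` computes the within-patient
rank statistic (average ranks on ties, with the standard tie
correction). For untied tables of modest size (k ≤ 5 conditions, up to
30 patients) the p value is exact: the permutation null — all k!ⁿ
equally likely within-block rank orders — is enumerated by dynamic
programming over column rank sums, which collapses the 6⁹ ≈ 10⁷ raw
orders of the package's own 9 × 3 design into a few hundred states.
The exact default is a deliberate choice: at 9 × 3 the asymptotic
chi-square test's measured type-I error is ≈5.9% at nominal 5%, while
the exact test attains ≈4.9%; the asymptotic path remains available and
is used automatically for tied or large tables.

Post-hoc pairwise comparisons use an exact paired sign-permutation test
on the within-patient differences (all 2ⁿ sign flips; zero differences
dropped), with Bonferroni multiplication over the number of pairs — the
original analysis names only "multiple comparison testing using a
Bonferroni correction", and the sign-permutation test is exact at n = 9
with no distributional assumptions. A Wilcoxon signed-rank alternative
is available. Pearson correlations (`pearson_with_p()`) use the
t-transform on n − 2 degrees of freedom.

On default synthetic cohorts this machinery reproduces the qualitative
significance pattern of the device study — the 0 mm Hg flow behavior
index separates from both oxygenated tensions far more often than 92
separates from 46 — asserted in the test suite as a frequency property
over seeds, never per seed.

## Numerical choices and problem sizes

* Fixed-point inversion: relative tolerance 10⁻⁸ on η₃, ≤100
  iterations, 0.5 damping on oscillation. The map is smooth and
  contracts in 3–6 iterations in practice.
* Forward root finding: `uniroot` on log₁₀Q₃ with bracket extension,
  tolerance 10⁻¹⁴.
* Diffusion: dz = 1 µm, dt = 0.05 s backward Euler; the acceptance-level
  simulation is a 200 s span (≈4000 steps, 316 nodes).
* Test-suite simulation sizes — 10⁴ null cohorts for the Friedman
  type-I calibration, 2×10⁴ for Pearson null uniformity, 10³ fits for
  power-law bias, 8 seeds for the significance-pattern property — were
  chosen to keep the full suite under a minute while leaving Monte-Carlo
  margins well inside the asserted tolerances.
* Degenerate inputs fail fast with specific errors: all-zero velocity
  traces, fewer than 3 pressure steps per tension, incomplete cohort
  tables, unstable explicit settings, non-square geometries routed to
  the square formula.

## Worked example

```{r example, eval = FALSE}
library(oxyrheo)

net <- default_device_network()
model <- build_blood_model(sample_composition(hbs = 0.95, hba = 0.02,
                                              hbf = 0.03))
trace <- generate_trace(model, net, seed = 1)
rheo <- infer_rheogram(trace, net)
fit_rheogram(rheo)

# cohort-level analysis, end to end
res <- run_pipeline(default_config(seed = 1))
res$friedman
res$pairwise
```

## Known limitations

* The single-fluid ratio assumption shared by generator and inversion
  (above): absolute viscosities on real devices inherit the original
  analysis's linearisation bias.
* The 1-D oxygen model omits lateral supply, so it mildly overestimates
  how fast deep layers equilibrate relative to the 3-D device; only the
  blood-channel timescale is targeted, at factor-2 tolerance.
* No yield-stress (Herschel–Bulkley/Casson) models: at 0 mm Hg the power
  law visibly degrades (lower, more scattered R²), and the fit object
  reports that degradation rather than modeling around it.
* Device constants and K magnitudes are illustrative defaults, not
  published values; analyses of real traces must supply the device's
  own geometry or constants.
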