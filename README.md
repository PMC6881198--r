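# oxyrheo

Oxygen-dependent microfluidic viscometry of sickle cell blood.

In sickle cell disease, falling oxygen tension polymerises hemoglobin S,
stiffens red cells, and raises the effective viscosity of whole blood —
the proximate driver of vaso-occlusion. A branching microfluidic device
measures this by perfusing blood through a 15 µm channel under
controlled oxygen tension and recording midline velocities over a series
of pressure steps. `oxyrheo` turns those measurements into
oxygen-resolved rheology, for researchers analysing data from such
devices or studying the inference problem itself:

- **Hydraulic network model.** The device is an inlet resistor in series
  with a bypass/experimental parallel pair,
  `R_hyd = c1*eta1 + 1/(1/(c2*eta2) + 1/(c3*eta3))`, with square-duct
  (`12*eta*L/(0.422*h^4)`) and rectangular
  (`12*eta*L/((1-0.63*h/w)*h^3*w)`) resistance formulas, valid in the
  creeping-flow regime (Re ≈ 0.014).
- **Rheogram inversion.** Effective viscosity vs average shear rate
  (γ̇ = u_max / 7.5 µm) per oxygen tension, by a fixed-point scheme over
  the sectional viscosity ratios `eta1 = A*eta3`, `eta2 = B*eta3`, where
  A and B are shear-rate ratios raised to (n − 1) for a power-law fluid.
- **Power-law rheology.** Flow behavior index n and consistency index K
  from the log-log regression of shear stress on shear rate
  (τ = K·γ̇ⁿ; n = 1 Newtonian, n < 1 shear-thinning), with R² as the
  goodness of fit, plus the fractional velocity change metric.
- **Oxygen transport.** A 1-D multilayer finite-volume diffusion solver
  for the device's vertical stack (glass | blood | PDMS membrane |
  hydration | PDMS membrane | gas), giving the time for the blood
  channel to reach anoxia after a gas switch, and the Stern–Volmer
  two-point calibration for the Ru(bpy)₃ oxygen dye.
- **Transfusion mixing.** Hemoglobin mass-balance arithmetic for
  sickle/donor mixtures at fixed hematocrit, and material-law
  interpolation with patient-specific sensitivity.
- **Cohort statistics.** Friedman repeated-measures test with exact
  small-sample p values (dynamic-programming enumeration of the
  permutation null), Bonferroni-corrected pairwise sign-permutation
  post hocs, and Pearson correlations.
- **Synthetic data.** A generator producing velocity traces with the
  statistical structure the analysis assumes — oxygen- and
  HbS-dependent power-law blood pushed through the full nonlinear
  forward model, 18 replicate captures per step with 5% multiplicative
  noise, 9-patient cohorts with realistic between-subject spread — so
  every stage is testable end to end without patient data.

## Worked example

```r
library(oxyrheo)

net   <- default_device_network()
model <- build_blood_model(sample_composition(hbs = 0.95, hba = 0.02,
                                              hbf = 0.03))
trace <- generate_trace(model, net, seed = 1)   # 3 tensions x 8 steps x 18 reps
rheo  <- infer_rheogram(trace, net)
fit_rheogram(rheo)
#>  po2_mmhg         n    K_pa_sn        r2 n_points
#>        92 0.7624927 0.01188320 0.9999170        8
#>        46 0.7408778 0.01616820 0.9998937        8
#>         0 0.8791366 0.02218308 0.9999296        8
```

The fitted flow behavior indices recover the generating material law
(anchors 0.76 / 0.74 / 0.87 at 92 / 46 / 0 mm Hg): viscosity rises and
shear-thinning weakens (n → 1) as oxygen falls — the rheologic
signature of deoxygenated sickle blood. The cohort-level pipeline adds
the repeated-measures statistics:

```r
res <- run_pipeline(default_config(seed = 1))
res$friedman
#> Friedman chi-squared = 12.67, df = 2, p = 0.0006579 (exact, 9 x 3)
res$pairwise
#>  condition_a condition_b      p_raw      p_adj significant
#>            0          46 0.00390625 0.01171875        TRUE
#>            0          92 0.01562500 0.04687500        TRUE
#>           46          92 0.12500000 0.37500000       FALSE
```

i.e. the 0 mm Hg indices differ from both oxygenated tensions while
92 vs 46 mm Hg do not — deoxygenation first raises viscosity without
changing the shear-thinning exponent, and only full anoxia degrades the
shear-thinning itself.

The oxygen-transport side:

```r
sim <- simulate_gas_switch(default_layer_stack(), gas_protocol(0, 0),
                           t_end_s = 200, initial_mmhg = 160)
time_to_anoxia(sim)   # ~53 s for the blood channel to fall below 2 mm Hg
```

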