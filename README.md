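# armioc — inverse optimal control quantification of arm-flexion motor control

`armioc` estimates the cost functional a person's motor system appears to
optimize while flexing the arm against gravity, from nothing more than a
motion-capture recording of the movement. It is aimed at motor-control and
rehabilitation researchers who want a compact, model-based quantifier of
neuromotor control — two numbers per subject — that can be compared across
subjects and groups (e.g. healthy controls versus patients with mild
neuromotor abnormalities).

## The model

The arm is a planar three-link chain (upper arm, forearm, hand) with state
`x = (θ₁, θ₂, θ₃, ω₁, ω₂, ω₃)` (joint angles from the hanging rest posture
and angular velocities) and joint torques `c` as controls. The neural
controller is modelled as the infinite-horizon linear quadratic regulator
minimizing

J = ∫₀^∞ ( xᵀ Z x + cᵀ U c ) dt,  Z = diag(θₚ, θₚ, θₚ, ωₚ, ωₚ, ωₚ),  U = I₃,

on the plant linearized at the raised (gravitationally unstable) target
posture. The optimal feedback is `c = c* − K(x − x*)` with `K = U⁻¹BᵀS` and
`S` the stabilizing solution of the algebraic Riccati equation
`SA + AᵀS − SBU⁻¹BᵀS + Z = 0`. The two penalties are the biomarkers:

- **θₚ** — penalty on angular displacement (how much the controller cares
  about being away from the target);
- **ωₚ** — penalty on angular velocity (how much it resists moving fast).

`armioc()` recovers `(θₚ, ωₚ)` by matching the model's vertical wrist
trajectory to the measured one (Nelder-Mead/golden-section over the log
weights, one Riccati solve per candidate). Downstream analyses include the
gain partition `τ = K₁x₁ + K₂x₂` with the principal velocity-resistance
direction `x₂*` and magnitude `τ*` (SVD of `K₂`), sinusoidal state
perturbations `c = −K(x + κ·cos(γt)·1)` summarized by cumulative
Wigner-Ville time-frequency energy, and Welch group comparisons of fitted
weights. A synthetic-recording generator with known ground truth makes the
whole pipeline testable without any data download.

## Worked example

```r
library(armioc)

# a synthetic subject at the patient-group preset weights, rendered to a
# 30 fps skeleton recording (5 s static window + 10 s movement), then fitted
syn <- synthetic_recording(preset_weights("patient"), noise_sd = 0, seed = 1)
fit <- armioc(syn$recording)
summary(fit)
#> Inverse optimal control fit of arm flexion
#>   theta_p = 1.40553e+07, omega_p = 5.28459e+06 (ratio 2.66)
#>   wrist trajectory error: 2.977e-05 m (l2 over 602 samples)
#>   converged: TRUE; scale identified from data: TRUE
#>   residual RMSE: 1.219e-05 m
#>   movement: 1.83 s, mean wrist speed 0.893 m/s, peak 2.802 m/s
#>   peak joint torques (N m): 11810, 8.721, 1.265
#>   principal velocity resistance tau* = 2300 along (0.939, 0.339, 0.0605)
```

The generating weights were θₚ = 13,950,617 and ωₚ = 5,245,197: both are
recovered within 1%, and the fitted ratio θₚ/ωₚ = 2.66 is exact to three
digits. The ratio is the robust readout — it sets the movement's time
constant (`≈ sqrt(θₚ/ωₚ)` per second); a patient-like controller (high
ratio, low ωₚ) moves faster and works harder than a control-like one. Under
realistic marker noise the overall weight *scale* is not identifiable and
the fit says so (`scale identified from data: FALSE`), anchoring the scale
at a reference level while still recovering the ratio; see the methods
vignette (`vignettes/arm-inverse-optimal-control.Rmd`) for the
identifiability analysis.

```r
# controller structure and perturbation response
stiffness(fit)
#> Velocity-resistance analysis of the feedback gain
#> tau* = 2299.68 (singular spectrum: 2299.7, 2298.9, 2298.8)
#> principal resisted velocity direction x2* (shoulder, elbow, wrist):
#> [1] 0.938770 0.339180 0.060527

sweep <- frequency_sweep(fit$linsys, fit$gain, freqs_hz = seq(0.5, 45.5, 5))
plot(sweep)   # low-frequency perturbations dominate the response energy
```

A group analysis is one call per stage:

```r
cohort <- synthetic_cohort(n_normal = 13, n_patient = 19, seed = 7)
fits <- lapply(seq_along(cohort$recordings), function(i)
  armioc(cohort$recordings[[i]]$recording,
         body_mass = cohort$truth$body_mass[i]))
compare_cohort(fits, cohort$truth$group)
```

A thin command-line interface over the same functions ships in
`inst/cli/armioc` (subcommands `synth`, `fit`, `stiffness`, `perturb`,
`compare`; see its header for usage).

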