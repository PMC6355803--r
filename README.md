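# trunkcoord

Forward-dynamic estimation of apparent axial trunk stiffness and
thorax–pelvis coordination during gait.

## The scientific problem

During walking, the thorax and pelvis rotate about the vertical axis in a
coordinated pattern: roughly in-phase at low speed, increasingly out-of-phase
(thorax lagging) as speed rises. Altered thorax–pelvis coordination has been
observed in several pathologies and is often read as a sign of increased
trunk stiffness — but arm swing also drives thorax rotation, so coordination
alone may be an ambiguous readout. `trunkcoord` is for movement scientists
who want to (i) estimate the *apparent* axial trunk stiffness and damping of
individual subjects from ordinary gait kinematics, (ii) quantify
coordination rigorously as frequency-response phase and gain, and (iii)
probe, in simulation, how stiffness and arm-swing moment each shape that
coordination.

## The model

The trunk is reduced to a single rotational degree of freedom: the thorax
(inertia *I* about the longitudinal axis through L5S1) is coupled to the
prescribed pelvis rotation θ<sub>P</sub>(t) by a linear torsion
spring–damper and driven by the arm-swing moment M<sub>arm</sub>(t):

```
I·θ̈_T = M_arm(t) − k·(θ_T − θ_P(t)) − b·(θ̇_T − θ̇_P(t))
```

* **k** (Nm/rad) and **b** (Nms/rad) are identified per subject by
  Nelder–Mead minimization of the RMSE between observed and simulated
  thorax rotations, started at (100 Nm/rad, 1 Nms/rad) with termination
  tolerance 10⁻⁴ on both the objective and the parameters.
* Coordination is the **frequency response function** from pelvis to thorax
  at the stride frequency (the spectral peak of pelvis rotation closest to
  1 Hz): its argument is the relative phase (negative = thorax lags), its
  modulus the gain (1 = equal amplitudes).
* An independent **inverse-dynamics route** estimates stiffness as the
  moment–angle regression slope, for cross-validation of the forward fit.
* A **synthetic cohort generator** produces gait recordings with known
  ground-truth parameters, so every stage is testable by parameter recovery.

For sinusoidal inputs the linear model has the closed-form steady state
`Θ_T = [(k + i·b·ω)·Θ_P + M_arm] / (k − I·ω² + i·b·ω)`, which serves as the
analytic oracle for the numerical integrator throughout the test suite.

## Worked example

```r
library(trunkcoord)

cfg  <- synthetic_subject_config(seed = 8)      # 120 s walk, truth k = 124, b = 5
subj <- generate_subject(cfg, subject_id = "demo")

fit <- fit_stiffness_damping(subj$recording, inertia = cfg$inertia)
fit
#> <trunk_fit> subject demo
#>   k = 124.11 Nm/rad, b = 5.015 Nms/rad (I = 0.200 kg m^2)
#>   RMSE 0.2174 deg, common variance 99.6%, 54 iterations

coordination_metrics(subj$recording)
#> <coordination_metrics> subject demo: f0 = 0.900 Hz, phase = -48.3 deg, gain = 1.248

sweep_coordination(subj$recording,
                   trunk_model_params(fit$stiffness, fit$damping, cfg$inertia),
                   target = "stiffness")
#> <coordination_sweep> subject demo, target stiffness (f0 = 0.900 Hz)
#>  factor relative_phase_deg     gain
#>    0.50          -81.19876 1.699899
#>    0.75          -60.87587 1.390840
#>    1.00          -48.29457 1.247959
#>    1.25          -39.82662 1.172072
#>    1.50          -33.78908 1.127256
```

Reading the output: the fit recovers the generating stiffness within 0.1%
(the 0.22° RMSE is the injected measurement noise); the subject walks with
the thorax lagging the pelvis by ~48° at the 0.9 Hz stride frequency; and
scaling stiffness from 0.5× to 1.5× pulls the phase monotonically toward 0°
(more in-phase) while the gain falls — the model's signature stiffness
effect. Sweeping `target = "arm_moment"` moves both metrics the opposite
way.

`run_pipeline()` chains all stages for a whole cohort (fits, coordination,
sweeps, estimator comparison, group checks, and the regression testing
whether phase/gain predict stiffness), writing tidy CSV/JSON tables. A thin
command-line wrapper with `synth`, `fit`, `coord`, `sweep`, `invstiff`,
`stats` and `run` subcommands is installed at
`system.file("cli", "trunkcoord-cli.R", package = "trunkcoord")`.

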