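# pulsedepth

Assessment of **pulse depth** from applanation tonometry recordings of
the radial artery.

In traditional pulse diagnosis the *floating* and *sunken* pulse
qualities describe whether the pulse is felt strongest under light or
heavy applied force — i.e. whether the pulse lies shallow or deep. Two
established quantifications read the depth off the pulse-amplitude
versus contact-pressure ("P–H") curve; a third reads it off the actual
travel of the sensor into the tissue. `pulsedepth` implements all
three, together with the complete signal-processing pipeline needed to
compute them from a raw pressure recording, and a fully seeded
synthetic tonometry simulator that provides ground truth for every
stage.

## The three indices

For a recording with per-beat pulse amplitudes *H* observed at contact
pressures *CP* and sensor displacements *SD*:

* **OCP / CFS_ocp** — the *optimal contact pressure* is the CP at which
  *H* peaks, normalised by the applied range:
  `CFS_ocp = (OCP − CP_min) / (CP_max − CP_min)` ∈ [0, 1].
* **CFS_pad** — the pulse-amplitude-difference coefficient. The CP
  range 60–195 mmHg is split into five equal sectors;
  with `H_shallow` the mean amplitude in the first sector and `H_deep`
  in the fifth, `CFS_pad = H_deep / (H_deep + H_shallow)` ∈ [0, 1].
* **PDI** — the *pulse depth index*, in millimetres: the sensor
  displacement from the skin-contact point to the point of maximal
  pulse amplitude, measured under a constant-velocity advance
  ("CETM": the actuator moves at 0.09 mm/s normal to the skin, so
  `SD = velocity × elapsed time`).

Because contact pressure grows nonlinearly with displacement (linear at
small SD, roughly quadratic beyond, diverging near arterial occlusion),
the SD-based PDI is *not* a reparameterisation of the CP-based indices;
characterising that nonlinearity (quadratic fit, log–log power-law
exponent) is part of the package (`cpsd_fit()`).

## Worked example

```r
library(pulsedepth)

# a synthetic constant-velocity recording whose true optimal depth is 4.2 mm
sim <- simulate_cetm(simulation_config(optimal_depth_mm = 4.2, seed = 42))
fit <- assess_depth(sim$recording)
print(fit)
#> Pulse depth assessment (cetm protocol)
#>   OCP       157.72 mmHg
#>   CFS_ocp    0.377
#>   CFS_pad    0.612
#>   PDI         4.02 mm

sim$truth$true_pdi_mm
#> [1] 4.2

# the contact-pressure vs displacement relation of the same recording
d <- extract_cpsd(sim$recording)
cpsd_fit(d$sd_mm[d$sd_mm > 0.2], d$cp_mmHg[d$sd_mm > 0.2])
#> Contact-pressure vs displacement fit
#>   CP = -4.365 + 13.639 sd + 7.073 sd^2   (R^2 = 0.9998)
#>   power-law exponent 1.731 on sd in [3.52, 6.85] mm
```

The PDI of 4.02 mm recovers the simulated 4.2 mm optimal depth to
within the beat-to-beat envelope resolution at the default noise level
(1 mmHg sensor noise, 3 mmHg respiration wander). The near-2 power-law
exponent reflects the quadratic-dominated stiffness of the default
tissue model.

Cohort-level comparisons (test–retest coefficient of variation, one-way
ANOVA with Duncan's multiple range test, pairwise R²) operate on the
table produced by `cohort_table(simulate_cohort(...))`; see
`cohort_summary()`.

A thin command-line interface over the same functions is installed at
`inst/cli/pulsedepth.R` with subcommands `simulate`, `assess`,
`cohort` and `cpsd`.

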