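# imugait

Running gait analysis from a single sacrum-mounted accelerometer, with the
force-plate gold standard and the full method-comparison statistics needed
to validate it.

## The problem

Peak vertical ground reaction force (**Fz,max**, in body weights), contact
time (**tc**), and flight time (**tf**) are key variables of running
biomechanics. The reference measurement is a force plate; in the field one
often only has an inertial measurement unit (IMU) on the runner's sacrum.
Because the sacrum rides near the centre of mass, Newton's second law turns
its vertical proper acceleration into an estimate of the vertical ground
reaction force:

    Fz(t) ≈ m · g0 · az(t)        (az in g; 1 g at rest, 0 g in flight)

`imugait` implements both measurement chains end to end:

* **GSM** (gold standard): plate force → 20 Hz 4th-order zero-phase
  Butterworth → foot-strike/toe-off events at a 20 N threshold →
  per-stride tc, tf, Fz,max (means over the 10 strides after the 30 s
  mark).
* **IMUM** (IMU method): tilt estimation from the 0.5 Hz-truncated gravity
  direction → reorientation onto the laboratory vertical → truncated
  Fourier filtering of the vertical axis to 5 Hz → force via `m·g0·az` →
  the same 20 N event detection and stride selection.
* **Agreement statistics**: Bland–Altman bias and limits of agreement
  `bias ± SRD` with 95% confidence intervals, smallest real difference
  `SRD = 1.96·σ_diff`, absolute and relative RMSE, proportional-bias
  regression, Cohen's *d*.
* **Simulator**: a seeded spring-mass treadmill-running generator emitting
  paired, unsynchronized (≤ 50 ms clock offset) force-plate and IMU traces
  with known ground truth — half-sine stances, stride-time jitter, sensor
  tilt, foot-strike impact transients, white noise, ±8 g saturation — so
  every stage is testable without access to laboratory data.

See `vignettes/imugait-methods.Rmd` for the models, parameter rationale,
and known limitations (in particular the systematic stance deformation a
5 Hz truncation necessarily introduces, and the corner-smearing of the
20 Hz plate filter on idealized half-sine stances).

## Worked example

```r
library(imugait)

trial <- generate_trial(sim_config(speed_kmh = 11, body_mass = 70,
                                   noise_sd_g = 0.05, impact_amp_g = 1,
                                   tilt_deg = 8, sync_offset_s = 0.03,
                                   seed = 42))
trial
#> <imu_trial> 41 s at 11 km/h: 102 cycles, mass 70 kg, tilt 8 deg

run_gsm(trial$force)$strides
#> <stride_variables> 10 strides: tc 286.9 ms, tf 113.0 ms, Fz,max 2.500 BW (means)
imum <- run_imum(trial$imu, body_mass = 70)
imum$rotation
#> <rotation3> tilt angle 0.1393 rad (7.98 deg)
imum$strides
#> <stride_variables> 10 strides: tc 327.7 ms, tf 72.4 ms, Fz,max 2.564 BW (means)
```

The simulated truth is tc ≈ 287 ms, tf ≈ 113 ms, Fz,max 2.5 BW. The gold
standard reproduces it; the IMU method recovers the 8° sensor tilt exactly
but — keeping only two harmonics of the ~2.5 Hz step waveform — widens
contact time by ~40 ms and raises the peak by ~0.06 BW. Quantifying that
kind of disagreement is what the agreement layer is for:

```r
cohort <- generate_cohort(12, speeds = c(9, 11, 13), seed = 42)
res    <- run_cohort(cohort)
report <- validate_agreement(res$pairs)
report[report$variable == "tc",
       c("speed_kmh", "n", "bias", "loa_lower", "loa_upper", "srd",
         "rmse_abs", "rmse_rel_pct", "cohens_d")]
#>   speed_kmh  n  bias loa_lower loa_upper   srd rmse_abs rmse_rel_pct cohens_d
#> 4         9 10 31.39     21.28     41.50 10.11    31.77        11.90    -1.15
#> 5        11 12 34.18     21.56     46.81 12.62    34.74        14.03    -1.32
#> 6        13 12 36.78     21.53     52.03 15.25    37.53        16.47    -1.76
```

One row per variable and speed: the IMU method overestimates contact time
by ~31–37 ms on this synthetic cohort (positive bias = overestimation),
with limits of agreement `bias ± SRD`, RMSE in ms and in % of the
gold-standard mean, and Cohen's *d* (negative sign: the gold-standard mean
is below the IMU mean). Flight time shows the mirror image — both methods
share toe-off events inside a common stride span, so what tc gains, tf
loses. `write_report()` serializes the table to nested JSON or flat CSV at
full double precision.

A command-line wrapper over the same functions ships in
`inst/cli/imugait`:

```sh
imugait simulate --out trials/ --seed 42
imugait gold     --force trials/trial001_force.csv --mass 70 --out gsm.csv
imugait estimate --imu   trials/trial001_imu.csv   --mass 70 --out imum.csv
imugait validate --pairs pairs.csv --out report.json
```

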