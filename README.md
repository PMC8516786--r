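# psatools

Tools for the **pupil-size artefact** (PSA): the spurious gaze deviation a
pupil-based video eye tracker reports when the pupil changes size while
the eye does not rotate. Pupil-minus-CR gaze estimation assumes the pupil
center is a fixed landmark of the eyeball; dilation and constriction break
that assumption, both physiologically (the pupil center migrates within
the iris) and optically (the camera sees the pupil through the refracting
cornea, and refraction deforms the pupil image differently at different
viewing angles). The artefact is summarized, per trial, by the slope *s*
(in °/mm) of a line fitted to gaze deviation versus pupil size.

The package is aimed at eye-tracking methodologists and provides three
connected pipelines plus the synthetic data to test them:

* **Optical simulation** (`eye_geometry()`, `ellipsoidal_eye()`,
  `build_calibration_lut()`, `simulate_psa()`): a 2-D horizontal-plane
  ray-tracing model of corneal refraction. The perceived pupil center is
  the mean of the image positions of the two refracted pupil-perimeter
  rays; a virtual tracker is calibrated at a 4 mm pupil by rotating the
  eye from −20° to 20° in 0.001° steps, and the artefact is the apparent
  minus the real orientation as the pupil sweeps 2–6 mm at fixed viewing
  angles.
* **Trace quantification** (`filter_trace()`, `median_center()`,
  `decile_curve()`, `run_psa_workflow()`): pupil-speed filtering (2 SD
  threshold, 20 ms gap padding), per-trial median centering, the
  seven-point decile curve (2nd–8th pupil-size deciles vs mean deviation
  in half-decile bands), and the least-squares slope in °/mm, with
  per-trial data-loss accounting.
* **Gaze estimation from eye images** (`detect_features()`,
  `fit_calibration()`, `apply_calibration()`): thresholding, 8-connected
  blob labeling, size/shape gates, binary centers of mass, the mean of
  the three lowest corneal reflections, and a second-order polynomial
  calibration from pupil-minus-CR vectors to target positions.
* **Synthetic data** (`gen_trace()`, `render_eye_image()`,
  `gen_viewing_grid()`): 0.125 Hz sinusoidal pupil trials with injected
  artefact slopes and blink transients, and rendered eye frames with
  exact sub-pixel ground truth.

## Worked example

Simulate the optical artefact for the default spherical eye (coarser
0.01° calibration grid for speed):

```r
library(psatools)
sim <- simulate_psa(eye_geometry(), camera_model(), step = 0.01)
sim
#> <psa_sim> sphere cornea; 5 viewing angles x 17 pupil diameters (d_cal = 4 mm)
#> Slopes of the optical pupil-size artefact (deg/mm):
#>  viewing_angle slope_deg_per_mm intercept_deg
#>            -12      0.005114807  -0.016534660
#>             -6      0.002739639  -0.009000379
#>              0      0.000000000   0.000000000
#>              6     -0.002739639   0.009000379
#>             12     -0.005114807   0.016534660
```

The artefact vanishes when the eye looks straight into the camera and at
the calibration diameter; its slope is positive when the gaze point is
left of the camera and negative to the right, decreasing monotonically
with viewing angle. `simulate_psa(ellipsoidal_eye(), ...)` runs the
elliptical-cornea variant, whose artefact runs in the opposite direction
(see the methods vignette for why the pupil-plane depth controls the
sign).

Quantify an injected artefact from a noisy, blink-laden synthetic trial:

```r
g <- gen_trace(trace_gen_config(injected_slope = -0.4, seed = 42))
tr <- median_center(filter_trace(g$trace))
data_loss_proportion(tr)
#> [1] 0.1055062
decile_curve(tr)
#> <psa_curve> horizontal component, 143119 valid samples
#>  pupil_decile_mm mean_deviation_deg
#>         2.793437       0.4735155800
#>         3.119275       0.3426977136
#>         3.516354       0.1847722377
#>         3.978795      -0.0006573839
#>         4.469124      -0.1940179569
#>         4.900630      -0.3659293430
#>         5.225868      -0.4962640056
#> slope: -0.3983 deg/mm, intercept: 1.5854 deg
```

The recovered slope (−0.398 °/mm) matches the injected −0.4 °/mm; the
data-loss proportion reflects the blinks plus the filter's transient
removal and gap padding.

The numbered scripts under `analysis/` run the full workflows and write
tables beneath `results/`: `01_simulate_optics.R` (deviation and slope
tables for both eye models, with figures), `02_trace_psa.R` (eight
viewing directions with an idiosyncratic offset plus a direction-dependent
slope, recovered to ±0.003 °/mm), `03_gaze_images.R` (ten-point
calibration on rendered frames; probe gaze errors below 0.01°).

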