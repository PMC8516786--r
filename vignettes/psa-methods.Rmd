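---
title: "Methods: modeling and quantifying the pupil-size artefact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and quantifying the pupil-size artefact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pupil-minus-CR video eye tracker estimates gaze from the vector between
the pupil center and one or more corneal reflections (CRs) in the camera
image. The method silently assumes that the pupil center is a fixed
landmark of the eyeball. It is not: when the pupil dilates or constricts
while the eye holds still, the tracker reports a spurious gaze shift — the
pupil-size artefact (PSA). The artefact has two components: an
idiosyncratic one, caused by physiological pupil-center migration during
dilation and visible even when the camera sits exactly on the line of
sight, and a viewing-direction-dependent one that grows with the angle
between the gaze direction and the camera axis. `psatools` implements
(i) an optical model of the viewing-direction-dependent component,
(ii) the trace-level quantification pipeline that turns a trial into a
slope in °/mm, (iii) a complete pupil-minus-CR image-analysis pipeline,
and (iv) generators for synthetic traces and eye images with exact ground
truth, so that every stage is testable end to end without recordings.

## The optical model

The model is strictly two-dimensional, living in the horizontal plane
through the eye's rotation center: one angular degree of freedom (the
viewing angle $\theta$, positive when the gaze point is right of the
camera), one image dimension. The eye is a single-surface schematic eye:

* a refracting corneal surface, circular (radius $R = 7.8$ mm) or
  elliptical in cross-section, with apex 13.5 mm in front of the rotation
  center;
* aqueous refractive index $n = 1.336$ behind the surface, air in front;
* a pupil in a flat plane at depth $z_p$ behind the apex, opening
  concentrically about the optic axis;
* an ideal pinhole camera at 530 mm, projecting rays onto a 1-D image
  line in proportion to the tangent of their incoming angle.

The camera cannot see the pupil itself, only its refracted image (the
entrance pupil). For a pupil of diameter $d$, the two in-plane perimeter
points sit at $\pm d/2$; a ray from each perimeter point refracts once at
the corneal surface (Snell's law, $n_1 \sin\alpha_i = n_2 \sin\alpha_t$)
and must pass through the pinhole. The solver parameterizes the surface by
the arc angle $\varphi$ and finds the exit point whose refracted ray hits
the pinhole: a coarse scan brackets the sign change of the signed miss
distance, followed by bisection to machine precision (Snell residuals and
miss distances at the solution are below $10^{-10}$; the solved exit point
agrees with an independent dense-grid search to better than $10^{-6}$ in
$\varphi$). The *perceived pupil center* is the mean of the two perimeter
image positions.

The virtual tracker is then calibrated exactly as the real procedure it
mimics: with the pupil fixed at $d_\mathrm{cal} = 4$ mm the eye is rotated
from $-20°$ to $20°$ in steps of $0.001°$, and the perceived center
recorded per angle into a strictly monotone look-up table (LUT). Linear
interpolation inverts it; at a $0.001°$ grid the interpolation error is
negligible against every quantity of interest. To simulate the artefact,
the eye is fixed at a viewing angle, the pupil swept from 2 to 6 mm, each
perceived center converted through the LUT to an *apparent* orientation,
and the deviation defined as apparent minus real orientation. By
construction the deviation vanishes at $d = d_\mathrm{cal}$ for every
angle and at $\theta = 0$ for every diameter (the frontal view refracts
both perimeter points symmetrically), and the whole deviation field is
antisymmetric in $\theta$ — the package tests assert all three properties.

### The pupil-plane depth decides the direction of the artefact

The interesting — and delicate — output is the sign of the artefact slope.
Sweeping the pupil-plane depth $z_p$ shows that the slope at $+12°$
crosses zero at $z_p \approx 2.65$ mm (for $R = 7.8$ mm): shallower pupil
planes give a negative slope at positive viewing angles (artefact slope
*decreasing* with viewing angle, the direction observed empirically with
real eye trackers), deeper ones give the opposite. Anatomically plausible
values span both sides of the crossover — the human anterior chamber is
roughly 2.5–4 mm deep and a single-surface reduced eye in any case has no
uniquely correct internal distances. We therefore fix the two bundled
geometries deliberately on opposite sides of the crossover:

* `eye_geometry()` (spherical, default) uses $z_p = 2.4$ mm, at the
  shallow end of the anatomical range, and yields slopes positive at
  negative viewing angles and negative at positive ones;
* `ellipsoidal_eye()` (elliptical corneal cross-section with semi-axes
  14.26 and 10.43 mm, apical radius ≈ 7.6 mm, no apex rotation, no pupil
  decentration) keeps the conventional $z_p = 3.6$ mm and yields the
  opposite direction.

Both choices are configuration, not physics: users probing their own
tracker geometry should treat $z_p$ as the first parameter to vary, and
the package deliberately reports the ellipsoidal variant's slopes rather
than asserting their sign. The simulated magnitudes (about 0.005–0.03
°/mm across $\pm12°$) are one to two orders of magnitude below typical
empirical artefact slopes, so corneal refraction alone cannot account for
the effect sizes seen in practice — the model isolates a mechanism, it
does not explain the phenomenon quantitatively.

## Quantifying the artefact from a trace

A trial is a uniformly sampled `signal_trace`: time, horizontal and
vertical calibrated deviation (degrees), pupil size, validity flag. The
pipeline runs in a fixed order:

1. **Velocity filtering.** A difference-of-window-means differentiator
   (two 20 ms windows, exact for linear ramps) produces a pupil-velocity
   signal. Samples whose pupil *speed* exceeds the mean speed by more
   than 2 SD (strictly; a zero-SD trace loses nothing) are invalidated,
   and every contiguous run of missing data is then widened by 20 ms on
   each side. The speed, not the signed velocity, is thresholded so that
   both the constriction ramp into a blink and the dilation ramp out of
   it are caught. The threshold, the removal count, and the pre-padding
   mask are stored with the trace, which makes the step auditable and
   idempotent: re-filtering a filtered trace removes nothing further.
2. **Median centering.** The per-trial median deviation is subtracted per
   component, discarding the calibration offset so trials are compared by
   shape.
3. **Decile curve.** The seven x-values are the 2nd–8th deciles of the
   valid pupil sizes (linear-interpolation quantiles); each y-value is
   the mean deviation of the samples in the half-decile band centered on
   that decile, $[Q((k-0.5)/10), Q((k+0.5)/10))$, so every sample between
   $Q(0.15)$ and $Q(0.85)$ contributes exactly once. An empty band (a
   degenerate pupil distribution) is an error naming the band.
4. **Slope.** An unweighted least-squares line through the seven points;
   the slope, in °/mm, is the artefact summary.

One bias is worth knowing about and is asserted in the tests rather than
ignored: for a *sinusoidally* modulated pupil the sample distribution is
arcsine-shaped, and the half-decile band means relate to the deciles by
the exact factor $c = \frac{20}{\pi}\sin\frac{\pi}{20} \approx 0.99589$,
so a true linear artefact of slope $s$ yields a decile-curve slope of
$c\,s$ — an attenuation of 0.4%, at most 0.003 °/mm over the realistic
slope range. For a uniformly distributed pupil the estimator is exact.
Parameter recovery over 50 noisy, blink-laden standard trials (slopes
drawn from ±0.7 °/mm, 0.1° noise, ~10% loss) achieves a mean absolute
error well below 0.02 °/mm.

## The synthetic trial generator

`gen_trace()` emulates the luminance-modulation trial: pupil
$4 + 1.5\sin(2\pi\,0.125\,t)$ mm over 160 s (20 cycles of 8 s) at
1000 Hz, a linear artefact injected into the horizontal deviation
relative to a 4 mm reference diameter, Gaussian deviation noise
(0.1° SD), and Poisson-scheduled blinks (12/min) as 300 ms gaps flanked
by 60 ms linear pupil ramps at 20 mm/s — steep enough to trip the speed
threshold, so the filter must remove the flanks, not just the gap. The
pupil-light relation is simplified to an in-phase sinusoid: physiological
response latency, asymmetry, and hippus are not modeled, which is
harmless here because the artefact statistic depends only on the joint
(pupil, deviation) distribution, not on temporal ordering. Passing tests
on these traces therefore demonstrates correctness of the estimator, not
realism of pupillometry. All randomness flows through an explicit seed.

## The image pipeline

`render_eye_image()` draws what a pupil-minus-CR tracker sees: a dark
pupil disk (anti-aliased by 4×4 supersampling) on a uniform iris, six
bright Gaussian CR spots in two rows of three, optional pixel noise, and
8-bit quantization; ground truth stores the exact sub-pixel centers.
Detection mirrors classical offline analysis: manual dark/bright
thresholds, 8-connected components, size and shape gates (area bounds,
moment-ellipse axis ratio ≤ 2, fill fraction ≥ 0.6 — the gates are
configuration, since no canonical values exist), binary centers of mass,
and the mean of the three *lowest* CRs in the image (largest y; ties
broken left-to-right) as the CR reference. Ten-bit input is right-shifted
to the 8-bit working depth. A second-order polynomial (terms
$1, x, y, x^2, xy, y^2$ per screen axis) maps pupil-minus-CR vectors to
target positions; at least six points in a layout spanning the quadratic
terms are required (three distinct levels per axis — a 2×n grid is
rank-deficient and rejected by name). On clean frames the pupil center is
recovered to better than 0.2 px and a known quadratic gaze map
round-trips to numerical precision; with 2-level pixel noise, probe-frame
gaze errors stay below 0.01°.

## Numerical choices and degenerate inputs

* Ray solve: bracket on a 81-point scan of the corneal cap, then 64
  bisection steps; total internal reflection and backward exits are
  masked out of the bracket, a missing sign change reports
  `no_solution`, a bracket hugging the cap boundary reports `occluded`.
* LUT: strict monotonicity is checked at build time and violations are
  an error (they indicate broken geometry, not data).
* Quantiles: type-7 (linear interpolation), R's default, used for both
  deciles and band edges.
* Gap padding rounds to the nearest whole sample; at 1000 Hz, 20 ms is
  exactly 20 samples.
* Line fits use the closed-form least-squares solution and are
  cross-checked against `lm()` in the tests.
* Problem sizes in the test-suite and acceptance runs: full-resolution
  40001-entry LUTs for the headline simulation, 0.01° grids for
  supporting checks; 50 × 160 s trials at 1000 Hz for slope recovery;
  320 × 240 px frames for the image pipeline.

## Known limitations

The optical model is 2-D: out-of-plane CR geometry, elliptical entrance
pupils, and the crystalline lens are out of scope, and the CR is not ray
traced at all (it forms by front-surface reflection and is unaffected by
corneal refraction, so the LUT maps perceived pupil center directly to
orientation). The idiosyncratic, pupil-center-migration component of the
artefact is deliberately absent from both the optical model and the
generator's ground truth — the generator injects it only as an abstract
linear slope. Simulated magnitudes under-predict empirical artefacts by
one to two orders of magnitude, and the direction of the simulated effect
is a function of the assumed internal eye geometry; conclusions about any
real tracker require fitting that geometry, which the configuration
surface exposes but the defaults cannot decide.
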