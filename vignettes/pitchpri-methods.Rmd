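---
title: "Methods: stereo reconstruction, release kinematics and the PRI correlation scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo reconstruction, release kinematics and the PRI correlation scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchpri)
```

`pitchpri` analyzes markerless two-camera recordings of baseball pitching:
it reconstructs the ball center and eight finger landmarks in 3D, extracts
the ball's release parameters and the ball–finger positional relationship
index (PRI), and asks — across pitchers — whether finger placement in the
final tens of milliseconds predicts release-angle variability. This
vignette documents the model, its assumptions, the tunable parameters, and
the numerical choices, in the order the pipeline applies them.

## Coordinate conventions and data model

All world coordinates are meters in a right-handed frame with the origin at
the center of the pitcher's plate, +x toward third base, +y toward home
plate, +z vertically up. A trial is a 60-frame window at 960 fps: 40 frames
before release, the release frame, and 19 after (the release frame is the
first frame on which the hand has visibly let go of the ball). Nine
landmarks are tracked per camera: the ball center plus the MP, PIP, DIP and
nail of the index and middle fingers, in DeepLabCut-style CSVs with a
tracking likelihood per observation.

## Camera model: 11-parameter DLT

Each camera is the classic direct linear transformation,

$$u = \frac{L_1 x + L_2 y + L_3 z + L_4}{L_9 x + L_{10} y + L_{11} z + 1},
\qquad
v = \frac{L_5 x + L_6 y + L_7 z + L_8}{L_9 x + L_{10} y + L_{11} z + 1},$$

without lens-distortion terms: the method targets outdoor, large-volume
setups with long lenses, where the linear model is the standard choice and
no distortion model is identifiable from a 27-point grid. Fitting uses the
standard two-equations-per-point linear system, solved by QR least squares
(not normal equations) for numerical stability; the condition number is
reported and a near-singular system (> 1e12) is refused. At least 6
non-coplanar points are required — coplanarity is diagnosed from the rank
of the centered point cloud. The reference calibration object is a 3×3×3
grid with 0.1 m spacing horizontally and along the throwing direction and
0.2 m vertically (27 points), anchored so it sits inside the reconstruction
volume near the release region (the anchor is a configuration parameter;
nothing in the method fixes it).

Triangulation stacks both cameras' equations into a 4×3 linear system per
point and solves by least squares; the reported residual is the norm of the
back-substitution error, ~0 for consistent observations. Inside
`reconstruct_trial()` thousands of frame–landmark pairs share one camera
pair, so the 3×3 normal equations are solved in closed form (Cramer's
rule), vectorized across points, with a determinant guard against
degenerate geometry; the scalar `dlt_triangulate()` keeps the QR path.

Observations with tracking likelihood below 0.9 (configurable) in either
view are treated as missing; gaps up to 3 frames (~3.1 ms) are filled by
linear interpolation and flagged, longer gaps fail the trial — mirroring
the practice of excluding unusable trials rather than guessing through
them.

## Filtering and differentiation

Positions are filtered per axis with a zero-phase low-pass Butterworth,
default 60 Hz cutoff and net order 4. "Fourth-order zero-phase" follows the
biomechanics convention: a 2nd-order filter run forward and backward, which
squares the magnitude response, so the design cutoff is raised to put the
net −3 dB point at the requested cutoff. The correction is applied on the
prewarped (tan) frequency axis, making it exact for the digital filter; a
`literal_order` switch runs the full order per pass (net 8th) for
sensitivity checks. Because the release event sits near the end of the
series, edge handling matters: series are extended by odd (point-symmetric)
reflection — which preserves level and slope, so ramps survive — plus
constant warm-up blocks that let the filter state reach steady state before
real data, making the DC response exact to machine precision.

Cutoff selection is supported by Winter-style residual analysis: the RMS
residual between raw and filtered series is computed over candidate
cutoffs, a straight line is fitted to the high-cutoff (noise-dominated)
tail, and the recommended cutoff is the lowest candidate whose residual
lies within one noise intercept of that line. A realizable filter never
passes the signal band exactly, so residuals below 0.5% of the raw signal
SD are treated as signal-preserving; a non-decaying or non-monotone tail
fails the analysis rather than extrapolating nonsense.

Velocity is the derivative of filtered position and acceleration the
derivative of velocity — acceleration is never taken directly from
position — using
central differences with second-order one-sided stencils at the endpoints —
exact for quadratics, so ballistic flight differentiates cleanly. Whether
filtering should be applied to positions or to derived velocities is not
fixed by the method description; per-axis position filtering before
differentiation is adopted and stated here as an assumption.

## Release detection and release parameters

Release is detected from the distance between the middle-finger nail and
the ball center: the first frame at which it exceeds ball radius + margin
and stays above for a hold period. Defaults: radius 0.0366 m (regulation
baseball — a configuration parameter, since the method itself does not fix
it), margin 5 mm, hold 3 frames; margin and hold were chosen to be robust
at ~1 px tracking noise, and the hold suppresses single-frame blips.
Detection runs on the *raw* reconstructed trajectories: the separation is a
step-like event, which is precisely what the low-pass filter smears across
frames. Automation replaces the visual identification used in manual
workflows, which the same distance criterion verified.

Release parameters come from the filtered velocity at the release sample
(not a post-release flight fit): speed = ‖v‖, elevation θ₁ = atan2(v_z,
v_y), azimuth θ₂ = atan2(v_x, v_y), both in (−90°, 90°) whenever the ball
moves toward the plate (v_y > 0; anything else is an implausible-release
error). Left-handed trials are mirrored — x positions, velocities and
accelerations negated, hence θ₂ and PRI x negated, speed, θ₁ and z
untouched — so all pitchers share the right-handed convention; mirroring is
an involution and is recorded in a flag.

The PRI is the nail position minus the ball center, in the global frame
(not hand-local coordinates), for both fingers and all three components.
Time-resolved quantities are resampled by linear interpolation from the
native 960 fps grid (1.0417 ms/frame) onto integer milliseconds over
[−40, 0] ms relative to release, because downstream statistics and
reporting are per-millisecond; linear interpolation is exact for lines and
O(Δt²) otherwise, well below measurement noise.

## Acceleration phase landmarks

On the release-locked vertical ball acceleration, three landmarks are
detected: the upward-acceleration peak (global maximum in a search window
of [−40, −15] ms, which excludes post-release rebound; the bounds are
configuration-exposed since the method specifies none), the last
positive-to-negative zero crossing after it (sub-ms by linear interpolation
between bracketing samples), and the downward-acceleration peak (global
minimum after the crossing). Peak times are refined to sub-ms by parabolic
interpolation; peak detection is invariant to constant offsets (the zero
crossing, by definition, is not). Trials with no crossing are flagged and
excluded from phase statistics. Across-trial summaries are per-trial
landmark times averaged with sample SD (n−1); averaging per-pitcher mean
curves first would be the alternative reading, and per-trial-then-average
is adopted.

The phase conventions are fixed windows relative to release: Phase 1
[−35, −30] ms (upward peak), Phase 2 [−30, −20] ms (zero crossing), Phase 3
[−9, −7] ms (downward peak).

## Across-pitcher statistics

Per pitcher, across-trial means and sample SDs (n−1 throughout) summarize
speed, both angles and release position; SDθ₁ and SDθ₂ are the
release-angle variabilities. The correlation scan computes, at each integer
millisecond and for each pairing of a per-pitcher PRI statistic (per-ms
mean or SD of the x or z component, either finger) with SDθ₁ or SDθ₂, the
across-pitcher Pearson r with the two-tailed p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on n−2 degrees of freedom. At n = 14 and
α = 0.05 this is equivalent to |r| ≥ 0.5324. No multiple-testing correction
is applied across the 41 time points — deliberately, for fidelity to the
raw per-time-point convention of this analysis style; a Benjamini–Hochberg
option exists but is off by default. Significant windows are maximal
contiguous runs of p < α. The index-finger and x-component scans are
computed and reported alongside the middle-finger z scans so that negative
results can be checked on synthetic data.

The cohort summary table reproduces per-pitcher mean ± SD rows plus an
overall row that is the mean and sample SD of the per-pitcher means,
following the per-pitcher columns exactly as given. In the bundled
reference table the overall x entry is inconsistent with the left-hander
inversion noted in its own caption (it matches the non-inverted x); the
summary follows the printed per-pitcher columns and the worked example
accordingly checks every overall entry except x.

## The synthetic study design

The generator emulates the full design: 14 pitchers (one left-handed) × 30
four-seam fastballs, recorded by two virtual cameras — one ~6 m behind the
pitcher, one ~7 m to the first-base side, both with 4000 px focal length
(≈1.5–2 mm per pixel in the release region) and optional Gaussian pixel
noise. Pitcher-level parameters are drawn inside the envelope observed in
collegiate cohorts: speeds 26.8–35.1 m/s, θ₁ means in [−7.5, 2.8]°, θ₂
means in [−9.0, −2.6]°, release positions around (0.15–1.0, 1.25–1.75,
1.45–1.85) m, between-trial angle SDs below ~2°.

The ball's pre-release vertical acceleration is modeled as a −g baseline
plus two Gaussian lobes (upward push, then downward pull). This family was
chosen because all of its kinematic integrals are closed-form in the normal
CDF/PDF, so ground-truth velocity and position are analytic, and the lobe
width of the upward component can be solved so the zero crossing lands
exactly at a scripted time. Scripted landmark times are drawn around 33.6
(up-peak), 22.8 (zero-cross) and 8.9 ms (down-peak) before release with
pitcher- and trial-level jitter. After release the flight is purely
ballistic: air drag and Magnus forces are omitted because only ~20 ms of
post-release flight is ever analyzed (a 35 m/s fastball loses ~0.25% of its
speed to drag in that time, far below the effects of interest) and gravity-
only flight keeps the free-flight oracle exact. Horizontal accelerations
are single broad low-amplitude lobes, producing no clear peaks — matching
the empirical observation that only the vertical channel has landmark
structure.

Fingers ride on the ball surface: each nail sits at the pitcher's mean PRI
direction plus per-trial placement noise and a slow angular drift, with the
radius carrying ~1 mm of clamped pad-compression jitter, so the grasp
constraint holds by construction; the other joints trail the nail at fixed
anatomical offsets. At release the nail separates along the velocity
direction at 14 m/s with a one-frame head start, so the scripted release
frame is exactly the first frame satisfying the distance criterion.

The across-pitcher effect is planted at the population level:
SDθ₁ = c₀ + c₁ · (mean middle-finger PRI z) + ε, with defaults c₀ =
0.82°, c₁ = 28°/m, ε ~ N(0, 0.28°), and PRI z drawn uniformly on
4–30 mm. These values were sized, before any end-to-end measurement, to
put SDθ₁ in the observed 0.74–1.81° envelope and the planted across-pitcher
correlation near 0.6. One consequence is worth stating plainly: a true
correlation of 0.6 at n = 14 gives the two-tailed Pearson test at α = 0.05
a theoretical power of only ~0.6, so any single simulated cohort has a
substantial chance of missing significance even though the pipeline
recovers the planted values essentially exactly — the power ceiling is a
property of the prescribed study size, not of the implementation. The
null-coupling variant (c₁ = 0) has a per-time-point false-positive rate at
the nominal α; note that when estimating that rate from simulated cohorts,
time points within one cohort are almost perfectly correlated, so the
estimator has roughly seed-level rather than time-point-level resolution.

What the generator does *not* emulate: articulated hand/arm dynamics,
spin and seam effects, tracking outliers and weather-dependent lighting
dropouts (likelihood degradation must be injected explicitly), camera
desynchronization, and lens distortion. Passing tests on synthetic data
therefore validate the geometry, signal processing, event detection and
statistics — not the robustness of any specific neural tracker.

All randomness flows from a single master seed through per-pitcher and
per-trial derived streams, so populations, trials and camera noise are
reproducible individually.

## Problem sizes and determinism

The test suite and the acceptance script exercise the full reference design
(14 pitchers × 30 trials) for recovery checks, and 20-seed batches of that
design for the planted-effect and null-rate checks; single-trial and
single-pitcher properties use smaller cohorts (4–6 trials) since the
quantities they check are deterministic given the seed. The file-based
pipeline is deterministic: identical inputs and configuration produce
byte-identical output tables, and its run log accounts for every input
trial as accepted or excluded with a reason.

## Known limitations

- The DLT has no distortion model; strongly distorting lenses would bias
  reconstruction in ways the synthetic tests cannot reveal.
- Release detection assumes a clean monotone separation; a ball clipped by
  the fingertips after release would register late.
- The correlation scan is across pitchers (n = cohort size): it inherits
  the low power of small-n correlation tests, and per-time-point
  significance without multiplicity correction should be read as
  descriptive, window-level evidence rather than confirmatory per-ms
  claims.
- The 1-ms alignment grid interpolates a 960 fps signal; features narrower
  than ~2 ms are not representable.
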