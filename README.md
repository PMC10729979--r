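# pitchpri

Markerless two-camera pitching kinematics and ball–finger positional
relationship analysis.

## The problem

In baseball pitching, the variability of the ball's velocity direction at
release — the release angle — is the main determinant of pitch-location
variability. Only the fingers touch the ball in the final milliseconds, so
the *positional relationship* between the fingertips and the ball center is
the natural candidate for explaining why some pitchers release the ball more
consistently than others. Measuring it requires reconstructing ball and
finger landmarks in 3D from synchronized high-speed video (960 fps) without
markers, then relating finger placement to across-trial release-angle
variability.

`pitchpri` implements that analysis chain for researchers in sports
biomechanics and motor control:

1. **Camera calibration and stereo reconstruction** — the 11-parameter
   direct linear transformation (DLT) is fitted per camera from a 27-point
   calibration grid and inverted pairwise to triangulate DeepLabCut-style 2D
   landmark tracks (ball center plus MP/PIP/DIP/nail of the index and middle
   fingers) into world coordinates: origin at the pitcher's plate, +x toward
   third base, +y toward home plate, +z up.
2. **Signal processing** — zero-phase 4th-order Butterworth low-pass at
   60 Hz (two passes of a 2nd-order filter with dual-pass cutoff
   correction), Winter-style residual analysis for cutoff selection, and
   second-order finite-difference velocity/acceleration.
3. **Release kinematics** — release detected from the middle-finger
   nail–ball distance (threshold = ball radius + margin with a hold
   hysteresis); release parameters: speed = |v|, elevation angle
   θ₁ = atan2(v_z, v_y), azimuth angle θ₂ = atan2(v_x, v_y); left-handed
   trials mirrored (x → −x, θ₂ → −θ₂) into a common convention.
4. **PRI** — the positional relationship index: nail position minus ball
   center, in the global frame, resampled onto a 1-ms grid over the final
   40 ms before release.
5. **Phase landmarks** — the ball's vertical acceleration shows an upward
   peak (~34 ms before release), a downward zero crossing (~23 ms) and a
   downward peak (~9 ms); the windows holding them define Phases 1–3.
6. **Correlation scan** — per millisecond, the across-pitcher Pearson r
   (with two-tailed p from the t transform, no multiplicity correction)
   between a per-pitcher PRI statistic (per-ms mean or SD of the x or z
   component) and the release-angle variabilities SDθ₁ / SDθ₂.
7. **Synthetic cohorts** — a generator that emulates the full study design
   (14 pitchers × 30 four-seam fastballs, two virtual cameras, analytic
   two-lobe acceleration profiles, fingers riding on the ball surface) with
   a *planted* across-pitcher coupling between mean middle-finger PRI z and
   SDθ₁, so every pipeline stage can be validated against known ground
   truth.

## Worked example

The package bundles the release-parameter summary of a reference cohort of
14 collegiate overarm pitchers. Reproducing its overall row:

```r
library(pitchpri)
summ <- summarize_release_parameters(reference_release_parameters())
round(subset(summ, pitcher == "Mean",
             c(speed_mean, speed_sd, theta1_deg_mean, theta1_deg_sd,
               theta2_deg_mean, theta2_deg_sd)), 2)
#>    speed_mean speed_sd theta1_deg_mean theta1_deg_sd theta2_deg_mean
#> 15      30.84     2.61           -0.14          2.67           -4.91
#>    theta2_deg_sd
#> 15          1.91
```

i.e. a mean release speed of 30.84 ± 2.61 m/s across pitchers, a mean
elevation release angle of −0.14 ± 2.67°, and a mean azimuth angle of
−4.91 ± 1.91° (negative = toward first base for a right-hander).

The bundled time-resolved correlation table, thresholded at the two-tailed
critical |r| for n = 14:

```r
round(critical_r(14), 4)
#> [1] 0.5324
scan <- reference_pri_correlation()
significant_windows(subset(scan, pairing == "Mean_z_middle_x_SDtheta1"))
#>                    pairing start_ms end_ms n_points
#> 1 Mean_z_middle_x_SDtheta1      -28    -22        7
```

The mean middle-finger PRI z-position correlates significantly with SDθ₁
over a contiguous window 22–28 ms before release — the lower the middle
finger sat on the ball in that window, the smaller the elevation-angle
variability.

An end-to-end synthetic run:

```r
co   <- simulate_cohort(n_pitchers = 14, n_trials = 30, coupling_c1 = 28, seed = 1)
scan <- correlation_scan(co$aggregates)
subset(scan, pairing == "Mean_z_middle_x_SDtheta1" & time_ms == -25,
       c(time_ms, r, p))
#>     time_ms         r           p
#> 508     -25 0.7451481 0.002225647
```

which recovers the planted positive coupling between finger height and
release-angle variability.

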