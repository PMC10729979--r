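test_that("release parameters follow the polar-angle definitions", {
  rp <- compute_release_parameters(c(0, 30, 0), c(0, 1.5, 1.7))
  expect_equal(rp$speed, 30)
  expect_equal(rp$theta1_deg, 0)
  expect_equal(rp$theta2_deg, 0)
  rp <- compute_release_parameters(c(0, 30, 30), c(0, 1.5, 1.7))
  expect_equal(rp$theta1_deg, 45)
  expect_equal(rp$theta2_deg, 0)
  expect_error(compute_release_parameters(c(1, -5, 0), c(0, 1.5, 1.7)),
               class = "pitchpri_implausible_release")
})

test_that("angles match a projection/arccos oracle on random velocities", {
  set.seed(21)
  for (i in 1:100) {
    v <- c(runif(1, -10, 10), runif(1, 5, 40), runif(1, -10, 10))
    rp <- compute_release_parameters(v, c(0, 1.5, 1.7))
    # oracle: project onto the plane, unsigned angle from arccos, sign from
    # the out-of-axis component
    th1 <- sign(v[3]) * acos(v[2] / sqrt(v[2]^2 + v[3]^2)) * 180 / pi
    th2 <- sign(v[1]) * acos(v[2] / sqrt(v[1]^2 + v[2]^2)) * 180 / pi
    expect_equal(rp$theta1_deg, th1, tolerance = 1e-10)
    expect_equal(rp$theta2_deg, th2, tolerance = 1e-10)
    # scale invariance of angles, linearity of speed
    rp2 <- compute_release_parameters(3.7 * v, c(0, 1.5, 1.7))
    expect_equal(rp2$theta1_deg, rp$theta1_deg, tolerance = 1e-10)
    expect_equal(rp2$theta2_deg, rp$theta2_deg, tolerance = 1e-10)
    expect_equal(rp2$speed, 3.7 * rp$speed, tolerance = 1e-10)
  }
})

test_that("release detection honors threshold, hold and failure modes", {
  n <- 60
  ball <- matrix(0, n, 3)
  nail <- matrix(0, n, 3)
  nail[, 3] <- 0.0366  # glued to the surface
  expect_error(detect_release(ball, nail), class = "pitchpri_no_release_detected")
  # scripted separation at frame 45
  sep <- nail
  sep[45:n, 3] <- 0.0366 + 0.01 * seq_len(n - 44)
  expect_equal(detect_release(ball, sep), 45L)
  # a single-frame blip is suppressed by hold_frames = 3
  blip <- nail
  blip[30, 3] <- 0.06
  blip[50:n, 3] <- 0.0366 + 0.01 * seq_len(n - 49)
  expect_equal(detect_release(ball, blip), 50L)
  # criterion met at the first frame warns about window misalignment
  far <- nail; far[, 3] <- 0.2
  expect_warning(detect_release(ball, far), class = "pitchpri_window_misaligned")
})

test_that("PRI is the global-frame nail minus ball difference", {
  n <- 20
  ball <- matrix(rnorm(3 * n), n, 3)
  expect_equal(compute_pri(ball, ball), matrix(0, n, 3), ignore_attr = TRUE)
  nail <- ball
  nail[, 3] <- nail[, 3] + 0.0366
  pri <- compute_pri(nail, ball)
  expect_equal(pri[, "z"], rep(0.0366, n))
  expect_equal(pri[, "x"], rep(0, n))
  expect_error(compute_pri(nail[1:10, ], ball), class = "pitchpri_alignment")
})

test_that("release-locked resampling is exact for lines and O(h^2) for sinusoids", {
  fs <- 960
  n <- 60
  const <- align_to_release(rep(2.5, n), fs, 41)
  expect_equal(const$time_ms, -40:0)
  expect_equal(const$values, rep(2.5, 41))
  lin <- align_to_release(seq_len(n) * 0.3, fs, 41)
  expect_equal(lin$values, 0.3 * (41 + (-40:0) * fs / 1000), tolerance = 1e-12)
  t <- (seq_len(n) - 41) / fs
  sine <- align_to_release(sin(2 * pi * 15 * t), fs, 41)
  oracle <- sin(2 * pi * 15 * (-40:0) / 1000)
  expect_lt(max(abs(sine$values - oracle)), (2 * pi * 15 / fs)^2)
  expect_error(align_to_release(rep(1, n), fs, 20), class = "pitchpri_window")
})

test_that("mirroring flips x-linked quantities only, and is an involution", {
  st <- make_single_trial()
  trial <- st$trial
  trial$handedness <- "left"
  trial$mirror_applied <- FALSE
  m <- mirror_for_handedness(trial)
  expect_true(m$mirror_applied)
  expect_equal(m$release_params$theta2_deg, -trial$release_params$theta2_deg)
  expect_equal(unname(m$release_params$release_pos[1]),
               -unname(trial$release_params$release_pos[1]))
  expect_equal(m$release_params$speed, trial$release_params$speed)
  expect_equal(m$release_params$theta1_deg, trial$release_params$theta1_deg)
  expect_equal(m$pri$series$middle[, "z"], trial$pri$series$middle[, "z"])
  expect_equal(m$pri$series$middle[, "x"], -trial$pri$series$middle[, "x"])
  expect_equal(m$trajectories$ball[, 1], -trial$trajectories$ball[, 1])
  # involution
  back <- mirror_for_handedness(m)
  expect_false(back$mirror_applied)
  expect_equal(back$release_params, trial$release_params)
  expect_equal(back$pri$series, trial$pri$series)
  # right-handers pass through unchanged
  r <- mirror_for_handedness(st$trial)
  expect_identical(r$release_params, st$trial$release_params)
  expect_false(r$mirror_applied)
  bad <- st$trial; bad$handedness <- "ambi"
  expect_error(mirror_for_handedness(bad), class = "pitchpri_invalid_metadata")
})

test_that("a left-handed release x of -0.17 m reads +0.17 m after inversion", {
  st <- make_single_trial()
  trial <- st$trial
  trial$handedness <- "left"
  trial$release_params$release_pos[1] <- -0.17
  m <- mirror_for_handedness(trial)
  expect_equal(unname(m$release_params$release_pos[1]), 0.17)
})

test_that("noiseless pipeline recovers release parameters and PRI offsets", {
  st <- make_single_trial()
  expect_equal(st$trial$release_index, st$truth$release_frame)
  expect_lt(abs(st$trial$release_params$speed - st$truth$release_params$speed),
            0.1)
  expect_lt(abs(st$trial$release_params$theta1_deg -
                  st$truth$release_params$theta1_deg), 0.2)
  expect_lt(abs(st$trial$release_params$theta2_deg -
                  st$truth$release_params$theta2_deg), 0.2)
  # trial-mean middle-finger PRI z close to the realized surface offset
  expect_lt(abs(mean(st$trial$pri$series$middle[, "z"]) -
                  st$truth$pri_offset$middle[3]), 0.004)
})
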