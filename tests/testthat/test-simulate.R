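test_that("population generation is reproducible and validates arguments", {
  p1 <- make_population(6, 28, seed = 5)
  p2 <- make_population(6, 28, seed = 5)
  expect_equal(p1, p2)
  expect_error(make_population(2), class = "pitchpri_config")
  expect_equal(length(p1), 6)
  for (p in p1) {
    expect_gt(p$speed_mean, 25); expect_lt(p$speed_mean, 36)
    expect_gt(p$theta1_mean, -8.01); expect_lt(p$theta1_mean, 3.01)
    expect_gt(p$sd_theta1, 0); expect_gt(p$sd_theta2, 0)
  }
})

test_that("the planted coupling has the scripted sign and vanishes at c1 = 0", {
  rhos <- vapply(1:10, function(s) {
    pop <- make_population(14, 28, seed = s)
    z <- vapply(pop, function(p) p$pri_offset$middle[["z"]], numeric(1))
    s1 <- vapply(pop, function(p) p$sd_theta1, numeric(1))
    cor(z, s1, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0))
  null_rhos <- vapply(1:20, function(s) {
    pop <- make_population(14, 0, seed = 1000 + s)
    z <- vapply(pop, function(p) p$pri_offset$middle[["z"]], numeric(1))
    s1 <- vapply(pop, function(p) p$sd_theta1, numeric(1))
    cor(z, s1)
  }, numeric(1))
  expect_lt(abs(mean(null_rhos)), 0.2)
})

test_that("ground-truth trials respect the grasp and consistency contracts", {
  pop <- make_population(5, 28, seed = 3)
  for (s in 1:10) {
    tr <- simulate_trial(pop[[1 + s %% 5]], seed = s)
    pre <- seq_len(tr$release_frame - 1)
    for (f in c("index_nail", "middle_nail")) {
      d <- sqrt(rowSums((tr$positions[[f]][pre, ] -
                           tr$positions$ball[pre, ])^2))
      expect_true(all(d <= 0.0366 + 0.02))
    }
    # the stated release parameters equal the realized release-frame velocity
    v <- tr$release_velocity
    expect_equal(tr$release_params$speed, sqrt(sum(v^2)), tolerance = 1e-9)
    expect_equal(tr$release_params$theta1_deg, atan2(v[3], v[2]) * 180 / pi,
                 tolerance = 1e-9)
    # post-release flight is exactly ballistic: second differences of z
    post <- tr$release_frame:nrow(tr$positions$ball)
    z <- tr$positions$ball[post, 3]
    h <- 1 / tr$fs
    az <- diff(diff(z)) / h^2
    expect_equal(az, rep(-9.81, length(az)), tolerance = 1e-6)
  }
})

test_that("generated profiles place their landmarks at the scripted times", {
  pop <- make_population(5, 28, seed = 13)
  for (s in 1:10) {
    tr <- simulate_trial(pop[[1 + s %% 5]], seed = 100 + s)
    expect_lt(max(abs(tr$landmarks_ms - tr$landmarks_scripted_ms)), 0.5)
    expect_true(tr$landmarks_ms["up_peak"] > tr$landmarks_ms["zero_cross"])
    expect_true(tr$landmarks_ms["zero_cross"] > tr$landmarks_ms["down_peak"])
  }
})

test_that("noise-free projection round-trips through the reconstruction", {
  st <- make_single_trial()
  raw <- reconstruct_trial(test_dlt_a, test_dlt_b, st$tracks$a, st$tracks$b)
  for (lm in pitch_landmarks()) {
    expect_lt(max(abs(raw[[lm]]$xyz - st$truth$positions[[lm]])), 1e-6)
  }
})

test_that("a camera aimed away from the scene raises a field-of-view error", {
  st <- make_single_trial()
  away <- make_virtual_camera(c(0, -6, 1.8), c(0, -20, 1.8))
  expect_error(project_trial(st$truth, list(a = away, b = test_cams$b)),
               class = "pitchpri_field_of_view")
})

test_that("calibration fixture has 27 points and sane noise behavior", {
  expect_equal(nrow(test_cal$points3d), 27)
  expect_lt(dlt_fit(test_cal, 1)$rmse_px, 1e-6)
  set.seed(6)
  rmses <- replicate(10, {
    noisy <- make_calibration_fixture(test_cams, sigma_px = 0.5)
    dlt_fit(noisy, 1)$rmse_px
  })
  expect_true(all(rmses > 0.1 & rmses < 2))
})

test_that("1-px tracking noise keeps median release-speed error under 0.5 m/s", {
  pop <- make_population(4, 28, seed = 17)
  set.seed(18)
  errs <- vapply(1:30, function(k) {
    tr <- simulate_trial(pop[[1 + k %% 4]], seed = 500 + k)
    tk <- project_trial(tr, test_cams, sigma_px = 1)
    an <- analyze_trial(test_dlt_a, test_dlt_b, tk$a, tk$b,
                        handedness = tr$handedness)
    abs(an$release_params$speed - tr$release_params$speed)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})
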