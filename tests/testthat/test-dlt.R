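test_that("noise-free DLT fit reproduces projections to numerical precision", {
  expect_lt(test_dlt_a$rmse_px, 1e-6)
  expect_lt(test_dlt_b$rmse_px, 1e-6)
  # refit recovers the generating coefficients (up to the common scale = 1)
  expect_equal(test_dlt_a$L, test_cams$a$L, tolerance = 1e-8)
  proj <- dlt_project(test_dlt_a, test_cal$points3d)
  expect_equal(proj, test_cal$observations[[1]], ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("fit rmse reflects injected observation noise", {
  set.seed(42)
  noisy <- test_cal
  for (k in 1:2) {
    noisy$observations[[k]] <- noisy$observations[[k]] +
      matrix(rnorm(54, 0, 1), ncol = 2)
  }
  fit <- dlt_fit(noisy, 1)
  expect_gt(fit$rmse_px, 0.3)
  expect_lt(fit$rmse_px, 3)
})

test_that("degenerate calibration geometries are rejected", {
  flat <- build_calibration_grid(c(0, 0, 0), 0.1, 0.1, 0.2, 3)
  flat[, "z"] <- 0.2  # coplanar
  obs <- dlt_project(test_cams$a$L, flat)
  expect_error(dlt_fit(calibration_set(flat, list(obs)), 1),
               class = "pitchpri_degenerate_calibration")
  few <- calibration_set(test_cal$points3d[1:5, ],
                         list(test_cal$observations[[1]][1:5, ]))
  expect_error(dlt_fit(few, 1), class = "pitchpri_degenerate_calibration")
})

test_that("projection follows the 11-parameter DLT equations", {
  L <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(dlt_project(L, c(0.3, 0.7, 0.2)), cbind(u = 0.3, v = 0.7))
  # constructed singular plane: L9 x = -1
  L2 <- c(1, 0, 0, 0, 0, 1, 0, 0, 2, 0, 0)
  expect_error(dlt_project(L2, c(-0.5, 0, 0)),
               class = "pitchpri_projection_singularity")
})

test_that("triangulation round-trips a known point through both cameras", {
  p <- c(0.35, 1.52, 1.68)
  tri <- dlt_triangulate(test_dlt_a, test_dlt_b,
                         dlt_project(test_cams$a$L, p),
                         dlt_project(test_cams$b$L, p))
  expect_lt(sqrt(sum((tri$point - p)^2)), 1e-6)
  expect_lt(tri$residual_m, 1e-6)
})

test_that("identical cameras give no parallax and fail", {
  p <- c(0.35, 1.52, 1.68)
  uv <- dlt_project(test_cams$a$L, p)
  expect_error(dlt_triangulate(test_dlt_a, test_dlt_a, uv, uv),
               class = "pitchpri_triangulation")
})

test_that("1-px pixel noise keeps median 3D error below 5 mm", {
  set.seed(7)
  errs <- replicate(100, {
    p <- c(runif(1, 0, 0.6), runif(1, 1.2, 1.8), runif(1, 1.3, 1.9))
    tri <- dlt_triangulate(
      test_dlt_a, test_dlt_b,
      dlt_project(test_cams$a$L, p) + rnorm(2),
      dlt_project(test_cams$b$L, p) + rnorm(2))
    sqrt(sum((tri$point - p)^2))
  })
  expect_lt(median(errs), 0.005)
})

test_that("linear triangulation agrees with reprojection-error grid search", {
  # independent oracle: exhaustive minimization of summed squared pixel
  # reprojection error over a 1-mm lattice around the true point
  set.seed(11)
  res_mm <- 0.001
  for (k in 1:20) {
    p <- c(runif(1, 0, 0.6), runif(1, 1.2, 1.8), runif(1, 1.3, 1.9))
    uva <- dlt_project(test_cams$a$L, p) + rnorm(2, 0, 0.5)
    uvb <- dlt_project(test_cams$b$L, p) + rnorm(2, 0, 0.5)
    tri <- dlt_triangulate(test_dlt_a, test_dlt_b, uva, uvb)
    off <- seq(-0.004, 0.004, by = res_mm)
    lattice <- as.matrix(expand.grid(p[1] + off, p[2] + off, p[3] + off))
    err <- rowSums((dlt_project(test_dlt_a, lattice) -
                      matrix(uva, nrow(lattice), 2, byrow = TRUE))^2) +
           rowSums((dlt_project(test_dlt_b, lattice) -
                      matrix(uvb, nrow(lattice), 2, byrow = TRUE))^2)
    best <- lattice[which.min(err), ]
    expect_lt(max(abs(tri$point - best)), res_mm + 1e-9)
  }
})

test_that("reprojection RMSE is invariant to calibration-point relabeling", {
  set.seed(3)
  perm <- sample(27)
  shuffled <- calibration_set(
    test_cal$points3d[perm, ],
    lapply(test_cal$observations, function(ob) ob[perm, ]))
  expect_equal(dlt_fit(shuffled, 1)$rmse_px, test_dlt_a$rmse_px,
               tolerance = 1e-9)
})

test_that("reconstruction recovers a trial and handles gaps", {
  st <- make_single_trial()
  raw <- reconstruct_trial(test_dlt_a, test_dlt_b, st$tracks$a, st$tracks$b)
  for (lm in pitch_landmarks()) {
    expect_lt(max(abs(raw[[lm]]$xyz - st$truth$positions[[lm]])), 1e-6)
  }
  # 2-frame likelihood dropout mid-trial: interpolated and flagged
  ta <- st$tracks$a
  ta$likelihood[25:26, "ball"] <- 0.1
  rec <- reconstruct_trial(test_dlt_a, test_dlt_b, ta, st$tracks$b)
  expect_true(all(rec$ball$interpolated[25:26]))
  expect_equal(sum(rec$ball$interpolated), 2)
  expect_lt(max(abs(rec$ball$xyz - st$truth$positions$ball)), 5e-4)
  # gap longer than max_gap fails the trial
  ta$likelihood[25:29, "ball"] <- 0.1
  expect_error(reconstruct_trial(test_dlt_a, test_dlt_b, ta, st$tracks$b),
               class = "pitchpri_unrecoverable_trial")
  # frame-count mismatch is a synchronization error
  tb <- st$tracks$b
  tb$u <- tb$u[1:59, ]; tb$v <- tb$v[1:59, ]; tb$likelihood <- tb$likelihood[1:59, ]
  expect_error(reconstruct_trial(test_dlt_a, test_dlt_b, st$tracks$a, tb),
               class = "pitchpri_synchronization")
})
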