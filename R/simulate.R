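# Synthetic pitcher populations, ground-truth trials, and virtual cameras.
#
# The reference design emulates a cohort of 14 overarm pitchers throwing 30
# four-seam fastballs each, recorded at 960 fps over a 60-frame window (40
# frames before release, the release frame, 19 after). The ball's
# pre-release vertical acceleration is a -g baseline plus two Gaussian
# lobes (an upward push followed by a downward pull), whose integrals are
# closed-form, so ground-truth velocity and position are analytic; after
# release the flight is purely ballistic (gravity only - drag and Magnus
# forces are irrelevant over the ~20 ms post-release window kept here).
# An across-pitcher coupling between the mean middle-finger PRI z-offset
# and the elevation-angle variability SDtheta1 is planted with known sign
# and size so the correlation scan can be validated end-to-end.

RELEASE_FRAME <- 41L
N_FRAMES <- 60L

# --- virtual cameras -------------------------------------------------------

#' Create a virtual DLT camera from pose and focal length
#'
#' Builds a pinhole camera at `position` looking at `target` and converts it
#' to the 11 DLT coefficients used throughout the package.
#'
#' @param position,target Length-3 world points (m).
#' @param focal_px Focal length in pixels (default 4000; about 1.5 mm per
#'   pixel at 6 m, matching a telephoto high-speed camera).
#' @param sensor_px Sensor size c(width, height) in pixels.
#' @param center_px Principal point (defaults to the sensor center).
#' @param sigma_px Gaussian pixel-noise SD used when projecting (default 0).
#' @param fps Frame rate (default 960).
#' @return Object of class `virtual_camera` with fields `L`, `sensor_px`,
#'   `sigma_px`, `fps`, `position`.
#' @export
make_virtual_camera <- function(position, target, focal_px = 4000,
                                sensor_px = c(2048, 1536), center_px = NULL,
                                sigma_px = 0, fps = 960) {
  stopifnot_finite(c(position, target), "camera pose")
  if (is.null(center_px)) center_px <- sensor_px / 2
  forward <- target - position
  fn <- sqrt(sum(forward^2))
  if (fn < 1e-9) ppr_stop("invalid_argument", "camera position equals target")
  forward <- forward / fn
  up <- c(0, 0, 1)
  right <- c(forward[2] * up[3] - forward[3] * up[2],
             forward[3] * up[1] - forward[1] * up[3],
             forward[1] * up[2] - forward[2] * up[1])
  rn <- sqrt(sum(right^2))
  if (rn < 1e-9) ppr_stop("invalid_argument", "camera looks straight up/down")
  right <- right / rn
  down <- c(forward[2] * right[3] - forward[3] * right[2],
            forward[3] * right[1] - forward[1] * right[3],
            forward[1] * right[2] - forward[2] * right[1])
  R <- rbind(right, down, forward)
  K <- rbind(c(focal_px, 0, center_px[1]),
             c(0, focal_px, center_px[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% position)
  if (abs(P[3, 4]) < 1e-9) {
    ppr_stop("invalid_argument", "camera center lies on the world origin plane")
  }
  P <- P / P[3, 4]
  structure(list(L = c(P[1, 1:4], P[2, 1:4], P[3, 1:3]),
                 sensor_px = sensor_px, sigma_px = sigma_px, fps = fps,
                 position = position, forward = forward),
            class = "virtual_camera")
}

#' Default two-camera rig
#'
#' One camera behind the pitcher, one to the first-base side, both aimed at
#' the release region, emulating a back + side high-speed camera placement.
#'
#' @param sigma_px Pixel-noise SD applied when projecting (default 0).
#' @return List with cameras `a` (back) and `b` (side).
#' @export
default_cameras <- function(sigma_px = 0) {
  list(
    a = make_virtual_camera(c(0.1, -6.0, 1.9), c(0.1, 1.5, 1.6),
                            sigma_px = sigma_px),
    b = make_virtual_camera(c(-7.0, 1.2, 1.6), c(0.3, 1.1, 1.6),
                            sigma_px = sigma_px)
  )
}

#' Calibration fixture for a camera pair
#'
#' Projects the 27-point calibration grid (0.1 / 0.1 / 0.2 m spacings along
#' x / y / z) through both cameras, optionally with pixel noise. The grid is
#' anchored so that it sits inside the reconstruction volume near the
#' release region.
#'
#' @param cameras List of two `virtual_camera` (as from [default_cameras()]).
#' @param origin Grid anchor corner (default c(0.2, 1.3, 1.35)).
#' @param sigma_px Observation noise SD in pixels (default 0).
#' @param dx_m,dy_m,dz_m,n_per_axis Grid geometry, see
#'   [build_calibration_grid()].
#' @return A [calibration_set()].
#' @export
make_calibration_fixture <- function(cameras, origin = c(0.2, 1.3, 1.35),
                                     sigma_px = 0, dx_m = 0.1, dy_m = 0.1,
                                     dz_m = 0.2, n_per_axis = 3) {
  grid <- build_calibration_grid(origin, dx_m, dy_m, dz_m, n_per_axis)
  obs <- lapply(cameras, function(cam) {
    uv <- dlt_project(cam$L, grid)
    check_in_sensor(uv, cam, "calibration grid", grid)
    if (sigma_px > 0) {
      uv <- uv + matrix(rnorm(length(uv), 0, sigma_px), ncol = 2)
    }
    uv
  })
  calibration_set(grid, unname(obs))
}

check_in_sensor <- function(uv, cam, what, points3d = NULL) {
  out <- uv[, 1] < 0 | uv[, 1] > cam$sensor_px[1] |
         uv[, 2] < 0 | uv[, 2] > cam$sensor_px[2]
  if (!is.null(points3d) && !is.null(cam$forward)) {
    depth <- sweep(as.matrix(points3d), 2, cam$position) %*% cam$forward
    out <- out | depth <= 0.05  # behind (or on) the camera
  }
  if (any(out)) {
    ppr_stop("field_of_view", "%s leaves the camera field of view (%d points)",
             what, sum(out))
  }
  invisible(uv)
}

# --- pitcher population ----------------------------------------------------

#' Generate a synthetic pitcher population
#'
#' Draws pitcher-level release-parameter distributions inside the envelope
#' observed in collegiate overarm cohorts (speeds 26-35 m/s, theta1 in
#' roughly \[-8, 3\] deg, theta2 in \[-9, -2.5\] deg), finger-placement (PRI)
#' offsets on the upper-rear ball surface, and a two-lobe vertical
#' acceleration profile with upward peak near 33.6 ms, zero crossing near
#' 22.8 ms and downward peak near 8.9 ms before release. The across-pitcher
#' effect is planted as
#' `SDtheta1 = c0 + c1 * (mean middle-finger PRI z) + eps`,
#' with `eps ~ N(0, sd_eps)`, so its sign and size are known.
#'
#' @param n_pitchers Number of pitchers (>= 3; reference design 14).
#' @param coupling_c1 Coupling slope in deg per m (default 28, sized to give
#'   a planted across-pitcher correlation near 0.6); 0 plants a null
#'   population.
#' @param seed Master seed; all pitcher- and trial-level randomness derives
#'   from it.
#' @param coupling_c0 Intercept in deg (default 0.82).
#' @param coupling_sd_eps Residual SD in deg (default 0.28).
#' @param n_left Number of left-handed pitchers (default 1 when
#'   `n_pitchers >= 4`, else 0), assigned to the last pitcher(s).
#' @return List of `pitcher_profile` objects.
#' @export
make_population <- function(n_pitchers = 14, coupling_c1 = 28, seed = 1,
                            coupling_c0 = 0.82, coupling_sd_eps = 0.28,
                            n_left = NULL) {
  if (n_pitchers < 3) {
    ppr_stop("config", "need at least 3 pitchers, got %d", n_pitchers)
  }
  if (coupling_sd_eps < 0) ppr_stop("config", "coupling_sd_eps must be >= 0")
  if (is.null(n_left)) n_left <- if (n_pitchers >= 4) 1L else 0L
  set.seed(seed)
  ids <- make_pitcher_ids(n_pitchers)
  lapply(seq_len(n_pitchers), function(i) {
    pri_mid_x <- runif(1, -0.012, 0.012)
    pri_mid_z <- runif(1, 0.004, 0.030)
    pri_idx_x <- pri_mid_x - 0.014
    pri_idx_z <- runif(1, 0.002, 0.020)
    sd_theta1 <- max(0.15, coupling_c0 + coupling_c1 * pri_mid_z +
                       rnorm(1, 0, coupling_sd_eps))
    t_up <- min(max(rnorm(1, -33.63, 1.0), -37), -30)
    t_dn <- min(max(rnorm(1, -8.88, 1.2), -12), -6.5)
    t_zc <- t_up + max(6, rnorm(1, 10.8, 2.0))
    t_zc <- min(t_zc, t_dn - 5)
    structure(list(
      id = ids[i],
      handedness = if (i > n_pitchers - n_left) "left" else "right",
      speed_mean = runif(1, 26.8, 35.1),
      speed_sd = runif(1, 0.25, 1.5),
      theta1_mean = runif(1, -7.5, 2.8),
      sd_theta1 = sd_theta1,
      theta2_mean = runif(1, -9.0, -2.6),
      sd_theta2 = runif(1, 0.45, 2.0),
      release_mean = c(x = runif(1, 0.15, 1.0), y = runif(1, 1.25, 1.75),
                       z = runif(1, 1.45, 1.85)),
      release_sd = c(x = 0.03, y = 0.04, z = 0.02),
      pri_offset = list(
        middle = c(x = pri_mid_x,
                   y = -sqrt(BALL_RADIUS_M^2 - pri_mid_x^2 - pri_mid_z^2),
                   z = pri_mid_z),
        index = c(x = pri_idx_x,
                  y = -sqrt(BALL_RADIUS_M^2 - pri_idx_x^2 - pri_idx_z^2),
                  z = pri_idx_z)
      ),
      pri_sd = runif(1, 0.002, 0.006),
      accel = list(t_up_ms = t_up, t_zc_ms = t_zc, t_dn_ms = t_dn,
                   a_up = runif(1, 180, 350), a_dn = runif(1, 120, 280),
                   sigma_dn_ms = 2.2),
      ay = list(C = runif(1, 380, 650), mu_s = -0.028, sigma_s = 0.009),
      ax = list(C = runif(1, -40, 40), mu_s = -0.022, sigma_s = 0.008),
      separation_speed = 14,
      trial_seed = sample.int(2^30, 1),
      coupling = c(c0 = coupling_c0, c1 = coupling_c1,
                   sd_eps = coupling_sd_eps)
    ), class = "pitcher_profile")
  })
}

make_pitcher_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else paste0("P", sprintf("%02d", seq_len(n)))
}

#' @export
print.pitcher_profile <- function(x, ...) {
  cat(sprintf(
    "<pitcher_profile> %s (%s): %.1f m/s, theta1 %.1f deg (SD %.2f), PRI z %.1f mm\n",
    x$id, x$handedness, x$speed_mean, x$theta1_mean, x$sd_theta1,
    1000 * x$pri_offset$middle["z"]))
  invisible(x)
}

# --- analytic trial motion -------------------------------------------------

# Gaussian-lobe kinematics: for a(t) = c0 + sum_i A_i exp(-(t-mu_i)^2/(2 s_i^2))
# on t <= 0, with state (p_rel, v_rel) at t = 0, velocity and position are
# closed-form in the normal CDF/PDF:
#   H(t)  = int_t^0 a ds
#   v(t)  = v_rel - H(t)
#   p(t)  = p_rel + v_rel t + int_t^0 H(s) ds
lobe_H <- function(t, A, mu, s) {
  A * s * sqrt(2 * pi) * (pnorm(-mu / s) - pnorm((t - mu) / s))
}
lobe_intH <- function(t, A, mu, s) {
  # int_t^0 H_lobe(s) ds with H_lobe as above
  G <- function(u) u * pnorm(u) + dnorm(u)
  A * s * sqrt(2 * pi) *
    (pnorm(-mu / s) * (-t) - s * (G(-mu / s) - G((t - mu) / s)))
}

axis_motion <- function(t, p_rel, v_rel, c0, lobes) {
  H <- -c0 * t
  intH <- c0 * t^2 / 2
  a <- rep(c0, length(t))
  for (lb in lobes) {
    H <- H + lobe_H(t, lb$A, lb$mu, lb$s)
    intH <- intH + lobe_intH(t, lb$A, lb$mu, lb$s)
    a <- a + lb$A * exp(-(t - lb$mu)^2 / (2 * lb$s^2))
  }
  list(p = p_rel + v_rel * t + intH, v = v_rel - H, a = a)
}

# Solve the up-lobe width so the profile crosses zero exactly at t_zc:
#   a_up exp(-(t_zc-t_up)^2 / (2 s_up^2)) = g + a_dn exp(-(t_zc-t_dn)^2/(2 s_dn^2))
solve_sigma_up <- function(t_up_s, t_zc_s, t_dn_s, a_up, a_dn, s_dn_s) {
  rhs <- GRAVITY_MS2 + a_dn * exp(-(t_zc_s - t_dn_s)^2 / (2 * s_dn_s^2))
  if (a_up <= rhs) {
    ppr_stop("config", "upward lobe (%.0f m/s^2) too weak to cross zero", a_up)
  }
  (t_zc_s - t_up_s) / sqrt(2 * log(a_up / rhs))
}

#' Simulate the ground truth of one trial
#'
#' Generates the 60-frame (40 pre-release + release + 19 post) ground truth
#' at 960 fps: the ball follows the profile's two-lobe vertical acceleration
#' until release and ballistic free flight afterwards; finger nails ride on
#' the rear-upper ball surface at the pitcher's PRI offsets (with per-trial
#' placement noise and a slow drift) until release and separate at the
#' profile's separation speed afterwards. Release speed and angles are drawn
#' from the profile's means and planted SDs. For left-handed profiles the
#' world x-axis quantities are mirrored.
#'
#' @param profile A `pitcher_profile`.
#' @param seed Trial seed (integer), or `NULL` to continue the current RNG
#'   stream.
#' @return Object of class `trial_ground_truth`: `positions` (named list of
#'   60 x 3 world-frame matrices per landmark), `fs`, `release_frame`,
#'   `release_params` (convention frame, i.e. mirrored for left-handers),
#'   `release_velocity`, `landmarks_ms` (true up-peak / zero-cross /
#'   down-peak, ms before release), `pri_offset` (realized trial offsets,
#'   convention frame), `handedness`.
#' @export
simulate_trial <- function(profile, seed = NULL) {
  if (!inherits(profile, "pitcher_profile")) {
    ppr_stop("invalid_argument", "profile must be a pitcher_profile")
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- 960
  t <- (seq_len(N_FRAMES) - RELEASE_FRAME) / fs
  pre <- t < 0

  # trial draws (convention frame: +x toward third base for a right-hander)
  speed <- rnorm(1, profile$speed_mean, profile$speed_sd)
  theta1 <- rnorm(1, profile$theta1_mean, profile$sd_theta1) * pi / 180
  theta2 <- rnorm(1, profile$theta2_mean, profile$sd_theta2) * pi / 180
  p_rel <- profile$release_mean + rnorm(3, 0, profile$release_sd)
  vy <- speed / sqrt(1 + tan(theta1)^2 + tan(theta2)^2)
  v_rel <- c(vy * tan(theta2), vy, vy * tan(theta1))

  # per-trial acceleration-profile jitter, order-preserving
  ac <- profile$accel
  t_up <- ac$t_up_ms + rnorm(1, 0, 0.5)
  t_dn <- min(max(ac$t_dn_ms + rnorm(1, 0, 0.5), -12.5), -6)
  t_zc <- min(max(ac$t_zc_ms + rnorm(1, 0, 0.8), t_up + 4), t_dn - 4)
  a_up <- ac$a_up * runif(1, 0.9, 1.1)
  a_dn <- ac$a_dn * runif(1, 0.9, 1.1)
  s_dn <- ac$sigma_dn_ms / 1000
  s_up <- solve_sigma_up(t_up / 1000, t_zc / 1000, t_dn / 1000,
                         a_up, a_dn, s_dn)
  z_lobes <- list(list(A = a_up, mu = t_up / 1000, s = s_up),
                  list(A = -a_dn, mu = t_dn / 1000, s = s_dn))
  y_lobes <- list(list(A = profile$ay$C, mu = profile$ay$mu_s,
                       s = profile$ay$sigma_s))
  x_lobes <- list(list(A = profile$ax$C, mu = profile$ax$mu_s,
                       s = profile$ax$sigma_s))

  ball <- matrix(NA_real_, N_FRAMES, 3, dimnames = list(NULL, c("x", "y", "z")))
  mx <- axis_motion(t[pre], p_rel[1], v_rel[1], 0, x_lobes)
  my <- axis_motion(t[pre], p_rel[2], v_rel[2], 0, y_lobes)
  mz <- axis_motion(t[pre], p_rel[3], v_rel[3], -GRAVITY_MS2, z_lobes)
  ball[pre, ] <- cbind(mx$p, my$p, mz$p)
  tp <- t[!pre]
  ball[!pre, ] <- cbind(p_rel[1] + v_rel[1] * tp,
                        p_rel[2] + v_rel[2] * tp,
                        p_rel[3] + v_rel[3] * tp - GRAVITY_MS2 * tp^2 / 2)

  # true acceleration landmarks of the generated profile (refined numerically
  # from the closed-form expression; shifts from the scripted times are tiny)
  az_fun <- function(tt) {
    -GRAVITY_MS2 + a_up * exp(-(tt - t_up / 1000)^2 / (2 * s_up^2)) -
      a_dn * exp(-(tt - t_dn / 1000)^2 / (2 * s_dn^2))
  }
  t_up_true <- stats::optimize(az_fun, c(t_up / 1000 - 3 * s_up,
                                         min(t_up / 1000 + 3 * s_up, 0)),
                               maximum = TRUE)$maximum
  t_dn_true <- stats::optimize(az_fun, c(max(t_dn / 1000 - 3 * s_dn, t_zc / 1000),
                                         0))$minimum
  t_zc_true <- uniroot(az_fun, c(t_up_true, t_dn_true))$root

  # finger placement: while grasped, each nail sits on the ball surface at
  # the pitcher's PRI direction plus per-trial placement noise and a slow
  # angular drift; the radius carries a clamped ~1 mm pad-compression
  # jitter, so the grasp constraint (and hence no early separation) holds
  # by construction. Joints trail the nail by fixed anatomical offsets.
  joint_off <- list(dip = c(0, -0.020, 0.008), pip = c(0, -0.043, 0.018),
                    mp = c(0, -0.068, 0.030))
  vhat <- v_rel / sqrt(sum(v_rel^2))
  sep <- profile$separation_speed
  positions <- list(ball = ball)
  offs <- list()
  for (f in c("index", "middle")) {
    base_dir <- profile$pri_offset[[f]] + rnorm(3, 0, profile$pri_sd)
    drift <- rnorm(3, 0, 0.03)
    radius <- BALL_RADIUS_M + max(min(rnorm(1, 0, 0.001), 0.002), -0.002)
    dirs <- cbind(base_dir[1] + drift[1] * (t + 0.02),
                  base_dir[2] + drift[2] * (t + 0.02),
                  base_dir[3] + drift[3] * (t + 0.02))
    surf <- dirs / row_norms(dirs) * radius
    off0 <- surf[RELEASE_FRAME, ]
    offs[[f]] <- off0
    nail <- ball
    nail[pre, ] <- ball[pre, , drop = FALSE] + surf[pre, , drop = FALSE]
    # separation has a one-frame head start: the release sample is the
    # first frame on which the hand has visibly let go
    nail[!pre, ] <- ball[!pre, , drop = FALSE] +
      matrix(off0, sum(!pre), 3, byrow = TRUE) -
      outer(tp + 1 / fs, vhat) * sep
    positions[[paste0(f, "_nail")]] <- nail
    positions[[paste0(f, "_dip")]] <- sweep(nail, 2, joint_off$dip, `+`)
    positions[[paste0(f, "_pip")]] <- sweep(nail, 2, joint_off$pip, `+`)
    positions[[paste0(f, "_mp")]] <- sweep(nail, 2, joint_off$mp, `+`)
  }
  positions <- positions[PITCH_LANDMARKS]

  release_params <- compute_release_parameters(v_rel, p_rel)
  if (profile$handedness == "left") {
    positions <- lapply(positions, function(m) { m[, 1] <- -m[, 1]; m })
  }
  structure(list(
    positions = positions, fs = fs, release_frame = RELEASE_FRAME,
    release_params = release_params, release_velocity = v_rel,
    landmarks_ms = c(up_peak = -1000 * t_up_true,
                     zero_cross = -1000 * t_zc_true,
                     down_peak = -1000 * t_dn_true),
    landmarks_scripted_ms = c(up_peak = -t_up, zero_cross = -t_zc,
                              down_peak = -t_dn),
    pri_offset = offs, handedness = profile$handedness,
    pitcher = profile$id
  ), class = "trial_ground_truth")
}

#' Project a ground-truth trial through a virtual camera pair
#'
#' Applies each camera's DLT projection to every landmark and frame, checks
#' the sensor bounds, adds Gaussian pixel noise of the given SD, and emits
#' DeepLabCut-style landmark series (likelihood 1 everywhere unless
#' degraded).
#'
#' @param truth A `trial_ground_truth`.
#' @param cameras List of two `virtual_camera`.
#' @param sigma_px Pixel-noise SD; defaults to each camera's own setting.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return List with [landmark_series()] `a` and `b`.
#' @export
project_trial <- function(truth, cameras, sigma_px = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(cameras, function(cam) {
    sp <- if (is.null(sigma_px)) cam$sigma_px else sigma_px
    n <- nrow(truth$positions[[1]])
    u <- matrix(NA_real_, n, length(PITCH_LANDMARKS),
                dimnames = list(NULL, PITCH_LANDMARKS))
    v <- u
    for (lm_name in PITCH_LANDMARKS) {
      uv <- dlt_project(cam$L, truth$positions[[lm_name]])
      check_in_sensor(uv, cam, sprintf("landmark %s", lm_name),
                      truth$positions[[lm_name]])
      u[, lm_name] <- uv[, 1]
      v[, lm_name] <- uv[, 2]
    }
    if (sp > 0) {
      u <- u + matrix(rnorm(length(u), 0, sp), nrow = n)
      v <- v + matrix(rnorm(length(v), 0, sp), nrow = n)
    }
    landmark_series(u, v, fs = truth$fs)
  })
  names(out) <- c("a", "b")
  out
}

# --- cohort drivers --------------------------------------------------------

#' Simulate and analyze a full cohort in memory
#'
#' Runs the complete study design end to end: population generation, trial
#' simulation, virtual-camera projection, reconstruction, filtering, release
#' detection, release parameters and PRI, mirroring, and per-pitcher
#' aggregation.
#'
#' @param n_pitchers,n_trials Cohort design (defaults 14 x 30).
#' @param coupling_c1 Planted coupling slope (see [make_population()]).
#' @param seed Master seed.
#' @param sigma_px Camera pixel noise SD (default 0).
#' @param cameras Camera pair (default [default_cameras()]).
#' @param cutoff_hz Butterworth cutoff passed to [analyze_trial()].
#' @return List with `population`, `truths` (per pitcher, list of
#'   `trial_ground_truth`), `trials` (per pitcher, list of
#'   `trial_kinematics`), and `aggregates` (list of `pitcher_aggregate`).
#' @export
simulate_cohort <- function(n_pitchers = 14, n_trials = 30, coupling_c1 = 28,
                            seed = 1, sigma_px = 0,
                            cameras = default_cameras(), cutoff_hz = 60) {
  population <- make_population(n_pitchers, coupling_c1, seed)
  cal <- make_calibration_fixture(cameras)
  dlt_a <- dlt_fit(cal, 1)
  dlt_b <- dlt_fit(cal, 2)
  truths <- list(); trials <- list(); aggregates <- list()
  for (pr in population) {
    set.seed(pr$trial_seed)
    trial_seeds <- sample.int(2^30, n_trials)
    p_truths <- vector("list", n_trials)
    p_trials <- vector("list", n_trials)
    for (k in seq_len(n_trials)) {
      truth <- simulate_trial(pr, trial_seeds[k])
      tracks <- project_trial(truth, cameras, sigma_px)
      p_truths[[k]] <- truth
      p_trials[[k]] <- analyze_trial(dlt_a, dlt_b, tracks$a, tracks$b,
                                     handedness = pr$handedness,
                                     cutoff_hz = cutoff_hz)
    }
    truths[[pr$id]] <- p_truths
    trials[[pr$id]] <- p_trials
    aggregates[[pr$id]] <- aggregate_trials(p_trials, pitcher = pr$id)
  }
  list(population = population, truths = truths, trials = trials,
       aggregates = aggregates)
}

#' Write a simulated cohort to CSV files
#'
#' Materializes a simulated scenario on disk in the formats the file-based
#' pipeline consumes: a calibration CSV, per-trial landmark CSVs for both
#' cameras (DeepLabCut dialect), a trials index, a ground-truth summary, and
#' a scenario YAML recording every generator setting.
#'
#' @param dir Output directory (created if missing).
#' @param n_pitchers,n_trials,coupling_c1,seed,sigma_px,cameras As in
#'   [simulate_cohort()].
#' @return `dir`, invisibly; side effect: files
#'   `calibration.csv`, `trials.csv`, `ground_truth.csv`, `scenario.yaml`,
#'   and `tracks/<pitcher>_<trial>_<cam>.csv`.
#' @export
simulate_cohort_csv <- function(dir, n_pitchers = 4, n_trials = 5,
                                coupling_c1 = 28, seed = 1, sigma_px = 0,
                                cameras = default_cameras()) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  population <- make_population(n_pitchers, coupling_c1, seed)
  cal <- make_calibration_fixture(cameras)
  write_calibration_csv(cal, file.path(dir, "calibration.csv"))
  index <- list(); gt <- list()
  for (pr in population) {
    set.seed(pr$trial_seed)
    trial_seeds <- sample.int(2^30, n_trials)
    for (k in seq_len(n_trials)) {
      truth <- simulate_trial(pr, trial_seeds[k])
      tracks <- project_trial(truth, cameras, sigma_px)
      fa <- file.path("tracks", sprintf("%s_%02d_a.csv", pr$id, k))
      fb <- file.path("tracks", sprintf("%s_%02d_b.csv", pr$id, k))
      write_landmark_csv(tracks$a, file.path(dir, fa))
      write_landmark_csv(tracks$b, file.path(dir, fb))
      index[[length(index) + 1]] <- data.frame(
        pitcher = pr$id, trial = k, handedness = pr$handedness,
        tracks_a = fa, tracks_b = fb)
      rp <- truth$release_params
      gt[[length(gt) + 1]] <- data.frame(
        pitcher = pr$id, trial = k, speed = rp$speed,
        theta1_deg = rp$theta1_deg, theta2_deg = rp$theta2_deg,
        x = rp$release_pos[1], y = rp$release_pos[2], z = rp$release_pos[3],
        up_peak_ms = truth$landmarks_ms["up_peak"],
        zero_cross_ms = truth$landmarks_ms["zero_cross"],
        down_peak_ms = truth$landmarks_ms["down_peak"])
    }
  }
  write.csv(do.call(rbind, index), file.path(dir, "trials.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, gt), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  yaml::write_yaml(list(n_pitchers = n_pitchers, n_trials = n_trials,
                        coupling_c1 = coupling_c1, seed = seed,
                        sigma_px = sigma_px),
                   file.path(dir, "scenario.yaml"))
  invisible(dir)
}
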