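# Release detection, release parameters, PRI, and handedness mirroring.
#
# World frame: origin at the center of the pitcher's plate, +x toward third
# base, +y toward home plate, +z up. Elevation angle theta1 = atan2(vz, vy),
# azimuth theta2 = atan2(vx, vy), both in degrees and in (-90, 90) whenever
# the ball travels toward the plate (vy > 0).

traj_xyz <- function(traj) {
  if (inherits(traj, "trajectory3d")) traj$xyz else as.matrix(traj)
}

#' Release parameters from the velocity vector at release
#'
#' @param velocity Length-3 velocity (m/s) at the release sample, world frame.
#' @param position Length-3 release position (m), world frame.
#' @return Object of class `release_parameters`: `speed` (m/s), `theta1_deg`
#'   (elevation, positive up), `theta2_deg` (azimuth, positive toward third
#'   base), `release_pos` (named x, y, z).
#' @examples
#' compute_release_parameters(c(0, 30, 30), c(0.4, 1.5, 1.7))$theta1_deg  # 45
#' @export
compute_release_parameters <- function(velocity, position) {
  stopifnot_finite(velocity, "velocity")
  stopifnot_finite(position, "position")
  if (length(velocity) != 3 || length(position) != 3) {
    ppr_stop("invalid_argument", "velocity and position must have length 3")
  }
  if (velocity[2] <= 0) {
    ppr_stop("implausible_release",
             "vy = %.3f m/s: ball is not moving toward home plate", velocity[2])
  }
  velocity <- unname(velocity); position <- unname(position)
  structure(list(
    speed = sqrt(sum(velocity^2)),
    theta1_deg = atan2(velocity[3], velocity[2]) * 180 / pi,
    theta2_deg = atan2(velocity[1], velocity[2]) * 180 / pi,
    release_pos = c(x = position[1], y = position[2], z = position[3])
  ), class = "release_parameters")
}

#' @export
print.release_parameters <- function(x, ...) {
  cat(sprintf(
    "<release_parameters> %.2f m/s, theta1 %.2f deg, theta2 %.2f deg at (%.2f, %.2f, %.2f) m\n",
    x$speed, x$theta1_deg, x$theta2_deg,
    x$release_pos[1], x$release_pos[2], x$release_pos[3]))
  invisible(x)
}

#' Detect the ball-release frame from the nail-ball separation
#'
#' Release is the first frame at which the distance between the middle-finger
#' nail and the ball center exceeds `ball_radius_m + margin_m` and stays
#' above it for `hold_frames` consecutive frames (hysteresis against
#' single-frame tracking blips).
#'
#' @param ball,middle_nail `trajectory3d` objects or n x 3 matrices, frame
#'   aligned.
#' @param ball_radius_m Ball radius in m (default regulation 0.0366).
#' @param margin_m Separation margin in m beyond the ball surface
#'   (default 0.005).
#' @param hold_frames Frames the criterion must persist (default 3).
#' @return Integer release frame index.
#' @export
detect_release <- function(ball, middle_nail, ball_radius_m = BALL_RADIUS_M,
                           margin_m = 0.005, hold_frames = 3) {
  b <- traj_xyz(ball); nl <- traj_xyz(middle_nail)
  if (nrow(b) != nrow(nl)) {
    ppr_stop("alignment", "ball and nail trajectories differ in length")
  }
  d <- row_norms(nl - b)
  thr <- ball_radius_m + margin_m
  above <- d > thr
  n <- length(above)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= hold_frames)
  if (!length(cand)) {
    ppr_stop("no_release_detected",
             "nail-ball distance never exceeds %.1f mm for %d consecutive frames",
             1000 * thr, hold_frames)
  }
  idx <- starts[cand[1]]
  if (idx == 1L) {
    ppr_warn("window_misaligned",
             "separation criterion already met at the first frame; trial window may start after release")
  }
  as.integer(idx)
}

#' Ball-finger positional relationship index (PRI)
#'
#' Per-frame vector difference between a finger-nail trajectory and the ball
#' center, expressed in the global frame (not hand-local coordinates).
#'
#' @param nail,ball `trajectory3d` objects or n x 3 matrices, frame aligned.
#' @return n x 3 matrix with columns x, y, z (m).
#' @export
compute_pri <- function(nail, ball) {
  nl <- traj_xyz(nail); b <- traj_xyz(ball)
  if (nrow(nl) != nrow(b)) {
    ppr_stop("alignment", "nail and ball trajectories differ in length")
  }
  out <- nl - b
  colnames(out) <- c("x", "y", "z")
  out
}

#' Resample a series onto the 1-ms release-locked grid
#'
#' Linearly interpolates a native-rate series (e.g. 960 fps) onto integer
#' milliseconds over `window_ms` relative to release; time 0 is the release
#' frame, negative times precede it.
#'
#' @param values Numeric vector sampled at `fs`.
#' @param fs Sampling rate in Hz.
#' @param release_index Sample index of release.
#' @param window_ms Length-2 window in ms relative to release
#'   (default c(-40, 0)).
#' @return List with `time_ms` (integer grid) and `values`.
#' @export
align_to_release <- function(values, fs, release_index,
                             window_ms = c(-40, 0)) {
  n <- length(values)
  if (release_index < 1 || release_index > n) {
    ppr_stop("window", "release_index %d outside series", release_index)
  }
  t_ms <- (seq_len(n) - release_index) / fs * 1000
  if (t_ms[1] > window_ms[1] || t_ms[n] < window_ms[2]) {
    ppr_stop("window",
             "series covers [%.1f, %.1f] ms; need [%g, %g] ms around release",
             t_ms[1], t_ms[n], window_ms[1], window_ms[2])
  }
  grid <- seq(window_ms[1], window_ms[2], by = 1)
  list(time_ms = grid, values = approx(t_ms, values, xout = grid)$y)
}

#' Mirror a left-handed trial into the right-handed convention
#'
#' Negates all x positions, velocities and accelerations, the PRI
#' x-components, the release x-position and the azimuth angle theta2 (whose
#' sign flips with +x). Right-handed trials pass through unchanged. Applying
#' the mirror twice restores the original trial.
#'
#' @param trial A `trial_kinematics` object (see [analyze_trial()]).
#' @return The trial, mirrored if left-handed, with `mirror_applied` toggled.
#' @export
mirror_for_handedness <- function(trial) {
  if (!inherits(trial, "trial_kinematics")) {
    ppr_stop("invalid_argument", "trial must be a trial_kinematics object")
  }
  if (is.null(trial$handedness) ||
      !trial$handedness %in% c("right", "left")) {
    ppr_stop("invalid_metadata", "handedness must be 'right' or 'left'")
  }
  if (trial$handedness == "right") {
    trial$mirror_applied <- FALSE
    return(trial)
  }
  flip_x <- function(m) { m[, 1] <- -m[, 1]; m }
  trial$trajectories <- lapply(trial$trajectories, flip_x)
  trial$velocity <- lapply(trial$velocity, flip_x)
  trial$acceleration <- lapply(trial$acceleration, flip_x)
  trial$release_params$theta2_deg <- -trial$release_params$theta2_deg
  trial$release_params$release_pos[1] <- -trial$release_params$release_pos[1]
  for (f in names(trial$pri$series)) {
    trial$pri$series[[f]][, "x"] <- -trial$pri$series[[f]][, "x"]
  }
  trial$mirror_applied <- !isTRUE(trial$mirror_applied)
  trial
}

#' Full single-trial analysis from two-camera tracks
#'
#' Runs reconstruction, filtering, differentiation, release detection,
#' release parameters, PRI extraction and (for left-handers) mirroring for
#' one trial.
#'
#' @param coeffs_a,coeffs_b Fitted `dlt_coefficients` of the two cameras.
#' @param tracks_a,tracks_b [landmark_series()] from each camera.
#' @param handedness `"right"` or `"left"`.
#' @param cutoff_hz,filter_order Butterworth settings (defaults 60 Hz,
#'   net order 4, zero phase).
#' @param ball_radius_m,margin_m,hold_frames Release-detection settings,
#'   see [detect_release()].
#' @param confidence_threshold,max_gap Reconstruction settings, see
#'   [reconstruct_trial()].
#' @param window_ms Release-locked analysis window (default c(-40, 0) ms).
#' @param mirror Mirror left-handed trials into the right-handed convention
#'   (default TRUE).
#' @return Object of class `trial_kinematics`: filtered `trajectories`,
#'   `velocity` and `acceleration` per landmark (n x 3 matrices),
#'   `release_index`, `release_params`, `pri` (release-locked 1-ms series
#'   per finger), `az_ms` (release-locked ball z-acceleration), `fs`,
#'   `handedness`, `mirror_applied`.
#' @export
analyze_trial <- function(coeffs_a, coeffs_b, tracks_a, tracks_b,
                          handedness = "right",
                          cutoff_hz = 60, filter_order = 4,
                          ball_radius_m = BALL_RADIUS_M, margin_m = 0.005,
                          hold_frames = 3,
                          confidence_threshold = 0.9, max_gap = 3,
                          window_ms = c(-40, 0), mirror = TRUE) {
  raw <- reconstruct_trial(coeffs_a, coeffs_b, tracks_a, tracks_b,
                           confidence_threshold, max_gap)
  fs <- tracks_a$fs
  # all 27 coordinate series share one filter design: stack, filter once
  stacked <- do.call(cbind, lapply(raw, `[[`, "xyz"))
  filt_all <- butter_lowpass(stacked, fs, cutoff_hz, filter_order,
                             zero_phase = TRUE)
  vel_all <- differentiate(filt_all, fs)
  acc_all <- differentiate(vel_all, fs)
  unstack <- function(m) {
    out <- lapply(seq_along(raw), function(i) {
      sub <- m[, 3 * i - (2:0), drop = FALSE]
      colnames(sub) <- c("x", "y", "z")
      sub
    })
    names(out) <- names(raw)
    out
  }
  filt <- unstack(filt_all)
  vel <- unstack(vel_all)
  acc <- unstack(acc_all)

  # Release is detected on the raw reconstructed distance: the separation
  # step is a discontinuity that low-pass filtering smears across frames.
  release_index <- detect_release(raw$ball, raw$middle_nail,
                                  ball_radius_m, margin_m, hold_frames)
  release_params <- compute_release_parameters(
    vel$ball[release_index, ], filt$ball[release_index, ])

  pri_series <- list()
  for (f in c("index", "middle")) {
    raw_pri <- compute_pri(filt[[paste0(f, "_nail")]], filt$ball)
    aligned <- vapply(1:3, function(j) {
      align_to_release(raw_pri[, j], fs, release_index, window_ms)$values
    }, numeric(diff(window_ms) + 1))
    colnames(aligned) <- c("x", "y", "z")
    pri_series[[f]] <- aligned
  }
  az <- align_to_release(acc$ball[, 3], fs, release_index, window_ms)

  trial <- structure(list(
    trajectories = filt, velocity = vel, acceleration = acc,
    release_index = release_index, release_params = release_params,
    pri = list(time_ms = az$time_ms, series = pri_series),
    az_ms = az$values, fs = fs,
    handedness = handedness, mirror_applied = FALSE
  ), class = "trial_kinematics")

  if (mirror) trial <- mirror_for_handedness(trial) else trial
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf(
    "<trial_kinematics> release frame %d, %.2f m/s, theta1 %.2f deg, theta2 %.2f deg%s\n",
    x$release_index, x$release_params$speed, x$release_params$theta1_deg,
    x$release_params$theta2_deg,
    if (isTRUE(x$mirror_applied)) " (mirrored)" else ""))
  invisible(x)
}
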