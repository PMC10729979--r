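# Vertical-acceleration phase landmarks.
#
# On the release-locked ball z-acceleration the pre-release profile shows an
# upward-acceleration peak, a downward zero crossing, and a
# downward-acceleration peak. The windows containing them across pitchers
# define Phase 1 ([-35, -30] ms), Phase 2 ([-30, -20] ms) and Phase 3
# ([-9, -7] ms) relative to release.

#' Phase window conventions
#'
#' @return Named list of length-2 ms windows (relative to release) for
#'   Phases 1-3.
#' @export
phase_windows <- function() {
  list(phase1 = c(-35, -30), phase2 = c(-30, -20), phase3 = c(-9, -7))
}

# Parabolic (three-point) refinement of an extremum on a unit grid.
refine_peak <- function(t, y, i) {
  if (i <= 1 || i >= length(y)) return(list(t = t[i], y = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < 1e-12) return(list(t = t[i], y = y[i]))
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  list(t = t[i] + delta * (t[2] - t[1]),
       y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Detect vertical-acceleration landmarks of one trial
#'
#' Finds, on the release-locked ball z-acceleration: the upward-acceleration
#' peak (global maximum in the search window, default `[-40, -15]` ms, which
#' excludes post-release rebound), the last positive-to-negative zero
#' crossing between the peaks (sub-ms by linear interpolation), and the
#' downward-acceleration peak (global minimum after the crossing). Peak
#' times are refined to sub-ms by parabolic interpolation.
#'
#' @param az_ms Numeric vector of ball z-acceleration (m/s^2) on the integer
#'   1-ms grid over `window_ms`.
#' @param window_ms Window covered by `az_ms` (default c(-40, 0)).
#' @param up_search_ms Search window for the upward peak
#'   (default c(-40, -15)).
#' @return Object of class `acceleration_landmarks`: `t_up_peak_ms`,
#'   `t_zero_cross_ms`, `t_down_peak_ms` (positive, "ms before release"),
#'   `a_up_ms2`, `a_down_ms2` (signed magnitudes).
#' @export
detect_landmarks <- function(az_ms, window_ms = c(-40, 0),
                             up_search_ms = c(-40, -15)) {
  grid <- seq(window_ms[1], window_ms[2], by = 1)
  if (length(az_ms) != length(grid)) {
    ppr_stop("invalid_argument",
             "az_ms must have %d samples on the 1-ms grid", length(grid))
  }
  stopifnot_finite(az_ms, "az_ms")
  up_idx <- which(grid >= up_search_ms[1] & grid <= up_search_ms[2])
  i_up <- up_idx[which.max(az_ms[up_idx])]
  up <- refine_peak(grid, az_ms, i_up)
  if (up$y <= 0) {
    ppr_stop("landmarks_not_found", "no positive upward-acceleration peak")
  }
  # provisional downward peak after the upward peak
  post <- seq(i_up + 1, length(grid))
  if (length(post) < 2) ppr_stop("landmarks_not_found", "no samples after up-peak")
  i_dn <- post[which.min(az_ms[post])]
  if (az_ms[i_dn] >= 0) {
    ppr_stop("landmarks_not_found",
             "acceleration never becomes negative after the upward peak")
  }
  # last +/- crossing between the peaks
  seg <- seq(i_up, i_dn)
  s <- az_ms[seg]
  cross <- which(s[-length(s)] > 0 & s[-1] <= 0)
  if (!length(cross)) {
    ppr_stop("landmarks_not_found",
             "no positive-to-negative crossing between the peaks")
  }
  k <- seg[max(cross)]
  t_zc <- grid[k] + az_ms[k] / (az_ms[k] - az_ms[k + 1]) * (grid[k + 1] - grid[k])
  # final downward peak strictly after the crossing
  post_zc <- which(grid > t_zc)
  i_dn <- post_zc[which.min(az_ms[post_zc])]
  dn <- refine_peak(grid, az_ms, i_dn)

  structure(list(
    t_up_peak_ms = -up$t, t_zero_cross_ms = -t_zc, t_down_peak_ms = -dn$t,
    a_up_ms2 = up$y, a_down_ms2 = dn$y
  ), class = "acceleration_landmarks")
}

#' @export
print.acceleration_landmarks <- function(x, ...) {
  cat(sprintf(
    "<acceleration_landmarks> up %.2f ms (%.1f m/s^2), zero-cross %.2f ms, down %.2f ms (%.1f m/s^2) before release\n",
    x$t_up_peak_ms, x$a_up_ms2, x$t_zero_cross_ms, x$t_down_peak_ms,
    x$a_down_ms2))
  invisible(x)
}

#' Across-trial landmark summary
#'
#' @param landmarks List of `acceleration_landmarks` (valid trials only).
#' @return data.frame with one row per landmark: mean and sample SD (n-1)
#'   of the times before release (ms), and of the signed magnitudes.
#' @export
summarize_landmarks <- function(landmarks) {
  landmarks <- Filter(Negate(is.null), landmarks)
  if (length(landmarks) < 2) {
    ppr_stop("insufficient_trials",
             "need at least 2 valid trials, got %d", length(landmarks))
  }
  grab <- function(field) vapply(landmarks, `[[`, numeric(1), field)
  rows <- list(
    up_peak = grab("t_up_peak_ms"),
    zero_cross = grab("t_zero_cross_ms"),
    down_peak = grab("t_down_peak_ms")
  )
  mags <- list(up_peak = grab("a_up_ms2"), zero_cross = NA_real_,
               down_peak = grab("a_down_ms2"))
  data.frame(
    landmark = names(rows),
    t_mean_ms = vapply(rows, mean, numeric(1)),
    t_sd_ms = vapply(rows, sd, numeric(1)),
    a_mean_ms2 = vapply(mags, function(m) if (all(is.na(m))) NA_real_ else mean(m),
                        numeric(1)),
    a_sd_ms2 = vapply(mags, function(m) if (all(is.na(m))) NA_real_ else sd(m),
                      numeric(1)),
    n = length(landmarks),
    row.names = NULL
  )
}
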