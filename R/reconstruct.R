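#' Construct a per-camera 2D landmark series
#'
#' Holds the pixel tracks of the nine landmarks over the frames of one trial
#' for one camera, with per-observation tracking likelihoods
#' (DeepLabCut-style).
#'
#' @param u,v n_frames x 9 matrices of pixel coordinates with landmark
#'   column names matching [pitch_landmarks()].
#' @param likelihood n_frames x 9 matrix in `[0, 1]`; defaults to all 1.
#' @param fs Sampling rate in Hz (default 960).
#' @return Object of class `landmark_series`.
#' @export
landmark_series <- function(u, v, likelihood = NULL, fs = 960) {
  u <- as.matrix(u); v <- as.matrix(v)
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(u), ncol(u), dimnames = dimnames(u))
  }
  likelihood <- as.matrix(likelihood)
  if (!identical(dim(u), dim(v)) || !identical(dim(u), dim(likelihood))) {
    ppr_stop("invalid_argument", "u, v and likelihood must share dimensions")
  }
  if (is.null(colnames(u))) colnames(u) <- PITCH_LANDMARKS[seq_len(ncol(u))]
  missing_lm <- setdiff(PITCH_LANDMARKS, colnames(u))
  extra_lm <- setdiff(colnames(u), PITCH_LANDMARKS)
  if (length(missing_lm) || length(extra_lm)) {
    ppr_stop("schema",
             "landmark set mismatch (missing: %s; unknown: %s)",
             paste(missing_lm, collapse = ","),
             paste(extra_lm, collapse = ","))
  }
  ord <- match(PITCH_LANDMARKS, colnames(u))
  colnames(v) <- colnames(u); colnames(likelihood) <- colnames(u)
  if (fs <= 0) ppr_stop("invalid_argument", "fs must be positive")
  structure(list(u = u[, ord, drop = FALSE], v = v[, ord, drop = FALSE],
                 likelihood = likelihood[, ord, drop = FALSE], fs = fs),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> %d frames x %d landmarks @ %g fps\n",
              nrow(x$u), ncol(x$u), x$fs))
  invisible(x)
}

new_trajectory3d <- function(landmark, xyz, fs, residual_m = NULL,
                             interpolated = NULL) {
  xyz <- as.matrix(xyz)
  colnames(xyz) <- c("x", "y", "z")
  n <- nrow(xyz)
  structure(list(landmark = landmark, xyz = xyz, fs = fs,
                 residual_m = residual_m %||% rep(0, n),
                 interpolated = interpolated %||% rep(FALSE, n)),
            class = "trajectory3d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct all landmark trajectories of one trial
#'
#' Triangulates every landmark frame-by-frame from a synchronized camera
#' pair. Frames whose tracking likelihood falls below `confidence_threshold`
#' in either view are treated as missing and linearly interpolated, provided
#' the gap does not exceed `max_gap` frames; longer gaps (or missing
#' endpoints that cannot be interpolated) fail the trial.
#'
#' @param coeffs_a,coeffs_b Fitted `dlt_coefficients` of the two cameras.
#' @param tracks_a,tracks_b [landmark_series()] from each camera; must have
#'   identical frame counts.
#' @param confidence_threshold Minimum likelihood to accept an observation
#'   (default 0.9).
#' @param max_gap Longest run of missing frames to gap-fill (default 3,
#'   about 3.1 ms at 960 fps).
#' @return Named list of `trajectory3d`, one per landmark, each carrying
#'   per-frame triangulation residuals and an `interpolated` flag.
#' @export
reconstruct_trial <- function(coeffs_a, coeffs_b, tracks_a, tracks_b,
                              confidence_threshold = 0.9, max_gap = 3) {
  if (!inherits(tracks_a, "landmark_series") ||
      !inherits(tracks_b, "landmark_series")) {
    ppr_stop("invalid_argument", "tracks must be landmark_series objects")
  }
  n <- nrow(tracks_a$u)
  if (nrow(tracks_b$u) != n) {
    ppr_stop("synchronization",
             "camera frame counts differ (%d vs %d)", n, nrow(tracks_b$u))
  }
  La <- if (inherits(coeffs_a, "dlt_coefficients")) coeffs_a$L else as.numeric(coeffs_a)
  Lb <- if (inherits(coeffs_b, "dlt_coefficients")) coeffs_b$L else as.numeric(coeffs_b)
  out <- vector("list", length(PITCH_LANDMARKS))
  names(out) <- PITCH_LANDMARKS
  for (lm_name in PITCH_LANDMARKS) {
    ok <- tracks_a$likelihood[, lm_name] >= confidence_threshold &
          tracks_b$likelihood[, lm_name] >= confidence_threshold &
          is.finite(tracks_a$u[, lm_name]) & is.finite(tracks_a$v[, lm_name]) &
          is.finite(tracks_b$u[, lm_name]) & is.finite(tracks_b$v[, lm_name])
    if (!any(ok)) {
      ppr_stop("unrecoverable_trial", "landmark %s has no usable frames", lm_name)
    }
    gaps <- missing_runs(ok)
    if (length(gaps$len) && max(gaps$len) > max_gap) {
      ppr_stop("unrecoverable_trial",
               "landmark %s has a %d-frame gap (max interpolatable %d)",
               lm_name, max(gaps$len), max_gap)
    }
    if (!ok[1] || !ok[n]) {
      ppr_stop("unrecoverable_trial",
               "landmark %s is missing at a trial boundary", lm_name)
    }
    tri <- dlt_triangulate_batch(
      La, Lb,
      tracks_a$u[ok, lm_name], tracks_a$v[ok, lm_name],
      tracks_b$u[ok, lm_name], tracks_b$v[ok, lm_name]
    )
    xyz <- matrix(NA_real_, n, 3)
    xyz[ok, ] <- tri$xyz
    res <- rep(NA_real_, n)
    res[ok] <- tri$residual_m
    if (any(!ok)) {
      frames <- seq_len(n)
      for (j in 1:3) {
        xyz[!ok, j] <- approx(frames[ok], xyz[ok, j], xout = frames[!ok])$y
      }
      res[!ok] <- 0
    }
    out[[lm_name]] <- new_trajectory3d(lm_name, xyz, tracks_a$fs,
                                       residual_m = res, interpolated = !ok)
  }
  out
}

# Run-length positions of FALSE stretches in a logical vector.
missing_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  list(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}
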