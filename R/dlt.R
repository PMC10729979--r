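# Direct linear transformation (DLT) camera model.
#
# The 11-parameter DLT maps a world point (x, y, z) to pixel coordinates:
#   u = (L1 x + L2 y + L3 z + L4) / (L9 x + L10 y + L11 z + 1)
#   v = (L5 x + L6 y + L7 z + L8) / (L9 x + L10 y + L11 z + 1)
# It is the classic linear camera model of close-range photogrammetry
# (no lens-distortion terms). Fitting is a linear least-squares problem with
# two equations per calibration point; triangulation from two calibrated
# cameras is the 4-equation, 3-unknown least-squares intersection.

# Rank of the centered 3D point cloud; < 3 means coplanar (or collinear).
point_cloud_rank <- function(points3d, tol = 1e-9) {
  centered <- sweep(points3d, 2, colMeans(points3d))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sum(sv > tol * max(sv[1], 1))
}

#' Fit the 11-parameter DLT camera model
#'
#' Solves the standard linear DLT system for one camera from >= 6
#' non-coplanar calibration points by QR-based least squares, and reports
#' the pixel reprojection RMSE over the calibration points.
#'
#' @param cal A [calibration_set()].
#' @param camera_index Which camera's observations to fit (1-based).
#' @return An object of class `dlt_coefficients`: list with `L` (numeric 11),
#'   `rmse_px`, and `condition_number` of the design matrix.
#' @export
dlt_fit <- function(cal, camera_index = 1) {
  if (!inherits(cal, "calibration_set")) {
    ppr_stop("invalid_argument", "cal must be a calibration_set")
  }
  if (camera_index < 1 || camera_index > length(cal$observations)) {
    ppr_stop("invalid_argument", "camera_index out of range")
  }
  pts <- cal$points3d
  obs <- cal$observations[[camera_index]]
  n <- nrow(pts)
  if (n < 6) {
    ppr_stop("degenerate_calibration",
             "at least 6 calibration points required, got %d", n)
  }
  if (point_cloud_rank(pts) < 3) {
    ppr_stop("degenerate_calibration",
             "calibration points are coplanar; the DLT system is rank deficient")
  }
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  u <- obs[, 1]; v <- obs[, 2]
  zero <- numeric(n); one <- rep(1, n)
  A <- rbind(
    cbind(x, y, z, one, zero, zero, zero, zero, -u * x, -u * y, -u * z),
    cbind(zero, zero, zero, zero, x, y, z, one, -v * x, -v * y, -v * z)
  )
  b <- c(u, v)
  sv <- svd(A, nu = 0, nv = 0)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > 1e12) {
    ppr_stop("conditioning",
             "DLT normal system is near singular (condition number %.3g)",
             kappa)
  }
  L <- as.numeric(qr.coef(qr(A), b))
  coeffs <- structure(
    list(L = L, rmse_px = NA_real_, condition_number = kappa),
    class = "dlt_coefficients"
  )
  proj <- dlt_project(coeffs, pts)
  coeffs$rmse_px <- sqrt(mean((proj - obs)^2))
  coeffs
}

#' @export
print.dlt_coefficients <- function(x, ...) {
  cat(sprintf("<dlt_coefficients> rmse %.4g px, condition number %.3g\n",
              x$rmse_px, x$condition_number))
  invisible(x)
}

#' Project world points through a DLT camera
#'
#' @param coeffs A `dlt_coefficients` object (or numeric vector of 11).
#' @param points3d n x 3 matrix (or length-3 vector) of world points (m).
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
dlt_project <- function(coeffs, points3d) {
  L <- if (inherits(coeffs, "dlt_coefficients")) coeffs$L else as.numeric(coeffs)
  if (length(L) != 11) {
    ppr_stop("invalid_argument", "DLT coefficients must have length 11")
  }
  p <- if (is.null(dim(points3d))) matrix(points3d, nrow = 1) else as.matrix(points3d)
  stopifnot_finite(p, "points3d")
  den <- L[9] * p[, 1] + L[10] * p[, 2] + L[11] * p[, 3] + 1
  if (any(abs(den) < 1e-12)) {
    ppr_stop("projection_singularity",
             "point lies on the camera's singular plane (zero DLT denominator)")
  }
  u <- (L[1] * p[, 1] + L[2] * p[, 2] + L[3] * p[, 3] + L[4]) / den
  v <- (L[5] * p[, 1] + L[6] * p[, 2] + L[7] * p[, 3] + L[8]) / den
  cbind(u = u, v = v)
}

#' Triangulate one point from two calibrated cameras
#'
#' Intersects the viewing rays implied by a pixel observation in each of two
#' DLT-calibrated cameras by least squares on the stacked 4 x 3 linear
#' system. The residual is the norm of the back-substitution error of that
#' system, ~0 for consistent noise-free observations.
#'
#' @param coeffs_a,coeffs_b `dlt_coefficients` for the two cameras.
#' @param uv_a,uv_b Length-2 pixel observations (u, v) in each camera.
#' @return List with `point` (named x, y, z in m) and `residual_m`.
#' @export
dlt_triangulate <- function(coeffs_a, coeffs_b, uv_a, uv_b) {
  La <- if (inherits(coeffs_a, "dlt_coefficients")) coeffs_a$L else as.numeric(coeffs_a)
  Lb <- if (inherits(coeffs_b, "dlt_coefficients")) coeffs_b$L else as.numeric(coeffs_b)
  stopifnot_finite(c(uv_a, uv_b), "pixel observations")
  A <- rbind(triang_rows(La, uv_a[1], uv_a[2]),
             triang_rows(Lb, uv_b[1], uv_b[2]))
  b <- c(uv_a[1] - La[4], uv_a[2] - La[8], uv_b[1] - Lb[4], uv_b[2] - Lb[8])
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    ppr_stop("triangulation",
             "degenerate two-view geometry (no parallax or identical cameras)")
  }
  xyz <- as.numeric(qr.coef(qr(A), b))
  res <- sqrt(sum((A %*% xyz - b)^2))
  list(point = c(x = xyz[1], y = xyz[2], z = xyz[3]), residual_m = res)
}

triang_rows <- function(L, u, v) {
  rbind(c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11]),
        c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11]))
}

# Vectorized two-view triangulation for many points (same camera pair).
# Solves the 3x3 normal equations per point with closed-form Cramer's rule;
# used by reconstruct_trial where thousands of frame-landmark pairs share
# one camera pair. Inputs are equal-length pixel vectors.
dlt_triangulate_batch <- function(La, Lb, ua, va, ub, vb) {
  n <- length(ua)
  # Row coefficients per equation k = 1..4: a_k x + b_k y + c_k z = d_k
  a1 <- La[1] - ua * La[9];  b1 <- La[2] - ua * La[10]; c1 <- La[3] - ua * La[11]
  a2 <- La[5] - va * La[9];  b2 <- La[6] - va * La[10]; c2 <- La[7] - va * La[11]
  a3 <- Lb[1] - ub * Lb[9];  b3 <- Lb[2] - ub * Lb[10]; c3 <- Lb[3] - ub * Lb[11]
  a4 <- Lb[5] - vb * Lb[9];  b4 <- Lb[6] - vb * Lb[10]; c4 <- Lb[7] - vb * Lb[11]
  d1 <- ua - La[4]; d2 <- va - La[8]; d3 <- ub - Lb[4]; d4 <- vb - Lb[8]
  # Normal equations M xyz = t
  m11 <- a1 * a1 + a2 * a2 + a3 * a3 + a4 * a4
  m12 <- a1 * b1 + a2 * b2 + a3 * b3 + a4 * b4
  m13 <- a1 * c1 + a2 * c2 + a3 * c3 + a4 * c4
  m22 <- b1 * b1 + b2 * b2 + b3 * b3 + b4 * b4
  m23 <- b1 * c1 + b2 * c2 + b3 * c3 + b4 * c4
  m33 <- c1 * c1 + c2 * c2 + c3 * c3 + c4 * c4
  t1 <- a1 * d1 + a2 * d2 + a3 * d3 + a4 * d4
  t2 <- b1 * d1 + b2 * d2 + b3 * d3 + b4 * d4
  t3 <- c1 * d1 + c2 * d2 + c3 * d3 + c4 * d4
  det <- m11 * (m22 * m33 - m23 * m23) -
         m12 * (m12 * m33 - m23 * m13) +
         m13 * (m12 * m23 - m22 * m13)
  scale <- pmax(abs(m11), abs(m22), abs(m33))^3
  bad <- !is.finite(det) | abs(det) < 1e-12 * pmax(scale, 1)
  if (any(bad)) {
    ppr_stop("triangulation",
             "degenerate two-view geometry for %d of %d points", sum(bad), n)
  }
  # Cramer's rule on the symmetric 3x3 system
  x <- (t1 * (m22 * m33 - m23 * m23) -
        m12 * (t2 * m33 - m23 * t3) +
        m13 * (t2 * m23 - m22 * t3)) / det
  y <- (m11 * (t2 * m33 - m23 * t3) -
        t1 * (m12 * m33 - m23 * m13) +
        m13 * (m12 * t3 - t2 * m13)) / det
  z <- (m11 * (m22 * t3 - t2 * m23) -
        m12 * (m12 * t3 - t2 * m13) +
        t1 * (m12 * m23 - m22 * m13)) / det
  r1 <- a1 * x + b1 * y + c1 * z - d1
  r2 <- a2 * x + b2 * y + c2 * z - d2
  r3 <- a3 * x + b3 * y + c3 * z - d3
  r4 <- a4 * x + b4 * y + c4 * z - d4
  list(xyz = cbind(x = x, y = y, z = z),
       residual_m = sqrt(r1^2 + r2^2 + r3^2 + r4^2))
}
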