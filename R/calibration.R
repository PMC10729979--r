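#' Build a regular 3D calibration grid
#'
#' Generates the lattice of known calibration points used to fit the DLT
#' camera models. The reference design is a 3 x 3 x 3 grid with 0.1 m
#' spacing along x (toward third base), 0.1 m along y (toward home plate)
#' and 0.2 m along z (vertical), giving 27 points.
#'
#' @param origin Numeric length-3, world position (m) of the grid corner.
#' @param dx_m,dy_m,dz_m Positive grid spacings in meters along x, y, z.
#' @param n_per_axis Number of points per axis (>= 2).
#' @return A matrix with `n_per_axis^3` rows and columns `x`, `y`, `z`,
#'   ordered x-fastest, then y, then z.
#' @examples
#' grid <- build_calibration_grid(c(0, 0, 0), 0.1, 0.1, 0.2, 3)
#' nrow(grid)  # 27
#' @export
build_calibration_grid <- function(origin = c(0, 0, 0),
                                   dx_m = 0.1, dy_m = 0.1, dz_m = 0.2,
                                   n_per_axis = 3) {
  stopifnot_finite(origin, "origin")
  if (length(origin) != 3) {
    ppr_stop("invalid_argument", "origin must have length 3")
  }
  if (!all(c(dx_m, dy_m, dz_m) > 0)) {
    ppr_stop("invalid_argument", "grid spacings must be positive")
  }
  if (n_per_axis < 2) {
    ppr_stop("invalid_argument", "n_per_axis must be at least 2")
  }
  idx <- seq_len(n_per_axis) - 1L
  g <- expand.grid(x = idx * dx_m, y = idx * dy_m, z = idx * dz_m,
                   KEEP.OUT.ATTRS = FALSE)
  out <- cbind(x = origin[1] + g$x, y = origin[2] + g$y, z = origin[3] + g$z)
  out
}

#' Construct a calibration set
#'
#' Pairs known 3D grid points with their observed 2D pixel coordinates in
#' each camera, index-aligned.
#'
#' @param points3d n x 3 matrix of world points (m).
#' @param observations List of n x 2 pixel matrices, one per camera.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(points3d, observations) {
  points3d <- as.matrix(points3d)
  if (ncol(points3d) != 3) {
    ppr_stop("invalid_argument", "points3d must have 3 columns")
  }
  stopifnot_finite(points3d, "points3d")
  if (!is.list(observations) || length(observations) < 1) {
    ppr_stop("invalid_argument", "observations must be a non-empty list")
  }
  observations <- lapply(observations, as.matrix)
  for (i in seq_along(observations)) {
    ob <- observations[[i]]
    if (ncol(ob) != 2 || nrow(ob) != nrow(points3d)) {
      ppr_stop("invalid_argument",
               "camera %d observations must be %d x 2", i, nrow(points3d))
    }
    stopifnot_finite(ob, sprintf("camera %d observations", i))
  }
  structure(list(points3d = points3d, observations = observations),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d points, %d cameras\n",
              nrow(x$points3d), length(x$observations)))
  invisible(x)
}

#' Read a calibration CSV
#'
#' Expects columns `point_id`, `X_m`, `Y_m`, `Z_m`, `cam`, `u_px`, `v_px`,
#' one row per point per camera.
#'
#' @param path Path to the CSV file.
#' @return A [calibration_set()].
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "X_m", "Y_m", "Z_m", "cam", "u_px", "v_px")
  if (!all(need %in% names(df))) {
    ppr_stop("parse", "calibration CSV must have columns: %s",
             paste(need, collapse = ", "))
  }
  cams <- sort(unique(df$cam))
  ids <- sort(unique(df$point_id))
  pts <- NULL
  obs <- vector("list", length(cams))
  for (ci in seq_along(cams)) {
    sub <- df[df$cam == cams[ci], , drop = FALSE]
    sub <- sub[order(sub$point_id), , drop = FALSE]
    if (!identical(sub$point_id, ids)) {
      ppr_stop("parse", "camera %s does not observe every point exactly once",
               cams[ci])
    }
    if (is.null(pts)) {
      pts <- cbind(x = sub$X_m, y = sub$Y_m, z = sub$Z_m)
    }
    obs[[ci]] <- cbind(u = sub$u_px, v = sub$v_px)
  }
  calibration_set(pts, obs)
}

#' Write a calibration set to CSV
#'
#' @param cal A [calibration_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(cal, path) {
  n <- nrow(cal$points3d)
  rows <- do.call(rbind, lapply(seq_along(cal$observations), function(ci) {
    data.frame(point_id = seq_len(n),
               X_m = cal$points3d[, 1],
               Y_m = cal$points3d[, 2],
               Z_m = cal$points3d[, 3],
               cam = ci,
               u_px = cal$observations[[ci]][, 1],
               v_px = cal$observations[[ci]][, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
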