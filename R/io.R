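# Landmark CSV readers/writers and bundled reference tables.

#' Read a 2D landmark CSV
#'
#' Two dialects are supported. The DeepLabCut dialect has three header rows
#' (scorer / bodyparts / coords) and per-landmark (x, y, likelihood) column
#' triplets, one row per frame. The flat dialect is long format with columns
#' `frame`, `landmark`, `u`, `v`, `likelihood`. Landmark names must match
#' [pitch_landmarks()] exactly.
#'
#' @param path CSV path.
#' @param dialect `"auto"` (default), `"deeplabcut"` or `"flat"`.
#' @param fs Sampling rate in Hz (default 960).
#' @return A [landmark_series()].
#' @export
read_landmark_csv <- function(path, dialect = c("auto", "deeplabcut", "flat"),
                              fs = 960) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ppr_stop("parse", "file not found: %s", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1)
    dialect <- if (grepl("^scorer", first)) "deeplabcut" else "flat"
  }
  if (dialect == "deeplabcut") read_landmark_dlc(path, fs)
  else read_landmark_flat(path, fs)
}

read_landmark_dlc <- function(path, fs) {
  raw <- tryCatch(
    read.csv(path, header = FALSE, stringsAsFactors = FALSE,
             colClasses = "character"),
    error = function(e) ppr_stop("parse", "cannot parse %s: %s", path,
                                 conditionMessage(e)))
  if (nrow(raw) < 4) ppr_stop("parse", "%s has no data rows", path)
  bodyparts <- as.character(raw[2, -1])
  coords <- as.character(raw[3, -1])
  data <- raw[-(1:3), , drop = FALSE]
  lm_names <- unique(bodyparts)
  mats <- list()
  for (cc in c("x", "y", "likelihood")) {
    cols <- which(coords == cc)
    if (length(cols) != length(lm_names)) {
      ppr_stop("parse", "%s: expected one '%s' column per landmark", path, cc)
    }
    m <- vapply(cols, function(j) as.numeric(data[[j + 1]]),
                numeric(nrow(data)))
    if (anyNA(m)) ppr_stop("parse", "%s: non-numeric %s values", path, cc)
    colnames(m) <- bodyparts[cols]
    mats[[cc]] <- m
  }
  landmark_series(mats$x, mats$y, mats$likelihood, fs = fs)
}

read_landmark_flat <- function(path, fs) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) ppr_stop("parse", "cannot parse %s: %s",
                                              path, conditionMessage(e)))
  need <- c("frame", "landmark", "u", "v", "likelihood")
  if (!all(need %in% names(df))) {
    ppr_stop("parse", "flat dialect needs columns: %s",
             paste(need, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  lms <- unique(df$landmark)
  shape <- function(col) {
    m <- matrix(NA_real_, length(frames), length(lms),
                dimnames = list(NULL, lms))
    m[cbind(match(df$frame, frames), match(df$landmark, lms))] <- df[[col]]
    if (anyNA(m)) ppr_stop("parse", "%s: missing frame/landmark cells", path)
    m
  }
  landmark_series(shape("u"), shape("v"), shape("likelihood"), fs = fs)
}

#' Write a landmark series as a DeepLabCut-dialect CSV
#'
#' @param series A [landmark_series()].
#' @param path Output path.
#' @param scorer Scorer header value (default "pitchpri").
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(series, path, scorer = "pitchpri") {
  lms <- colnames(series$u)
  header1 <- c("scorer", rep(scorer, 3 * length(lms)))
  header2 <- c("bodyparts", rep(lms, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(lms)))
  n <- nrow(series$u)
  body <- matrix("", n, 1 + 3 * length(lms))
  body[, 1] <- as.character(seq_len(n) - 1L)
  for (j in seq_along(lms)) {
    body[, 3 * j - 1] <- format(series$u[, j], digits = 17, trim = TRUE)
    body[, 3 * j] <- format(series$v[, j], digits = 17, trim = TRUE)
    body[, 3 * j + 1] <- format(series$likelihood[, j], digits = 17,
                                trim = TRUE)
  }
  lines <- c(paste(header1, collapse = ","),
             paste(header2, collapse = ","),
             paste(header3, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a landmark series as a flat long-format CSV
#'
#' @param series A [landmark_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_flat_csv <- function(series, path) {
  lms <- colnames(series$u)
  n <- nrow(series$u)
  df <- data.frame(
    frame = rep(seq_len(n) - 1L, times = length(lms)),
    landmark = rep(lms, each = n),
    u = as.vector(series$u),
    v = as.vector(series$v),
    likelihood = as.vector(series$likelihood)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- bundled reference tables ---------------------------------------------

#' Reference cohort release-parameter table
#'
#' Published per-pitcher release-parameter summary (mean and between-trial
#' SD of speed, elevation angle theta1, azimuth angle theta2 and release
#' position) for a reference cohort of 14 collegiate overarm pitchers
#' throwing 30 four-seam fastballs each, left-hander mirrored into the
#' right-handed convention. Used as a worked example for
#' [summarize_release_parameters()].
#'
#' @return data.frame with columns `pitcher`, `handedness` and
#'   `<param>_mean` / `<param>_sd` for speed, theta1_deg, theta2_deg, x, y,
#'   z.
#' @export
reference_release_parameters <- function() {
  read.csv(system.file("extdata", "reference_release_parameters.csv",
                       package = "pitchpri"),
           stringsAsFactors = FALSE)
}

#' Reference cohort PRI correlation scan
#'
#' Published time-resolved across-pitcher correlation coefficients (n = 14)
#' between middle-finger PRI z statistics (per-ms mean and SD) and the
#' release-angle variabilities SDtheta1 / SDtheta2, at each integer
#' millisecond from 40 ms before release to release. Used for
#' significance-threshold logic tests and as a worked example for
#' [significant_windows()].
#'
#' @param long If `TRUE` (default) return long format with columns
#'   `pairing`, `time_ms`, `r`, `n`, `p` (p recomputed from r and n via the
#'   t transform); otherwise the wide four-column table.
#' @return data.frame; see `long`.
#' @export
reference_pri_correlation <- function(long = TRUE) {
  wide <- read.csv(system.file("extdata", "reference_pri_correlation.csv",
                               package = "pitchpri"),
                   stringsAsFactors = FALSE)
  if (!long) return(wide)
  cols <- c(mean_z_sdtheta1 = scan_pairing_label("middle", "z", "mean", "theta1"),
            mean_z_sdtheta2 = scan_pairing_label("middle", "z", "mean", "theta2"),
            sd_z_sdtheta1 = scan_pairing_label("middle", "z", "sd", "theta1"),
            sd_z_sdtheta2 = scan_pairing_label("middle", "z", "sd", "theta2"))
  out <- do.call(rbind, lapply(names(cols), function(cn) {
    data.frame(pairing = cols[[cn]], time_ms = wide$time_ms, r = wide[[cn]],
               n = 14L)
  }))
  out$p <- pearson_p_from_r(out$r, 14)
  rownames(out) <- NULL
  out
}
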