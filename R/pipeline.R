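# File-based pipeline orchestration: calibrate -> reconstruct -> filter ->
# detect release -> mirror -> release parameters / PRI -> acceleration
# landmarks -> per-pitcher aggregation -> across-pitcher correlation scan.
# Trials that fail any stage are excluded with a logged reason, never
# silently dropped; the run aborts only if fewer than 3 pitchers retain at
# least 2 accepted trials.

default_pipeline_config <- function() {
  list(
    paths = list(calibration = NULL, trials = NULL, output_dir = NULL),
    filter = list(cutoff_hz = 60, order = 4, zero_phase = TRUE),
    release = list(ball_radius_m = BALL_RADIUS_M, margin_m = 0.005,
                   hold_frames = 3),
    reconstruction = list(confidence_threshold = 0.9, max_gap = 3),
    window_ms = c(-40, 0),
    alpha = 0.05,
    fs = 960
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Rolling polynomial hash (mod 2^31 - 1) of the deparsed config, for
# run-log provenance; stays within exact double-precision integer range.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full file-based analysis pipeline
#'
#' Reads a calibration CSV and a trials index, analyzes every trial, writes
#' all per-trial and cohort-level output tables plus a machine-readable run
#' log, and returns the cohort objects. Outputs are deterministic given
#' identical inputs and configuration.
#'
#' The trials index CSV must have columns `pitcher`, `trial`, `handedness`,
#' `tracks_a`, `tracks_b` (track paths relative to the index file's
#' directory or absolute).
#'
#' @param config Configuration list, or path to a YAML file with the same
#'   structure. Required: `paths$calibration`, `paths$trials`,
#'   `paths$output_dir`. Optional groups: `filter` (cutoff_hz, order),
#'   `release` (ball_radius_m, margin_m, hold_frames), `reconstruction`
#'   (confidence_threshold, max_gap), `window_ms`, `alpha`, `fs`.
#' @return Invisibly, a list with `aggregates`, `scan`, `windows`,
#'   `summary`, `landmark_summary`, `log`. Side effect: CSVs
#'   (`release_parameters.csv`, `pri.csv`, `landmarks.csv`, `summary.csv`,
#'   `scan.csv`, `windows.csv`) and `run_log.json` under
#'   `paths$output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  for (p in c("calibration", "trials", "output_dir")) {
    if (is.null(cfg$paths[[p]])) ppr_stop("config", "paths$%s is required", p)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    ppr_stop("config", "alpha must be in (0, 1)")
  }
  dir.create(cfg$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  base_dir <- dirname(cfg$paths$trials)

  cal <- read_calibration_csv(cfg$paths$calibration)
  dlt_a <- dlt_fit(cal, 1)
  dlt_b <- dlt_fit(cal, 2)

  index <- read.csv(cfg$paths$trials, stringsAsFactors = FALSE)
  need <- c("pitcher", "trial", "handedness", "tracks_a", "tracks_b")
  if (!all(need %in% names(index))) {
    ppr_stop("config", "trials index must have columns: %s",
             paste(need, collapse = ", "))
  }
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }

  log_rows <- list(); trial_rows <- list(); pri_rows <- list()
  lm_rows <- list(); trials_by_pitcher <- list(); lms_by_pitcher <- list()
  for (i in seq_len(nrow(index))) {
    row <- index[i, ]
    status <- "accepted"; reason <- ""
    trial <- tryCatch({
      ta <- read_landmark_csv(resolve(row$tracks_a), fs = cfg$fs)
      tb <- read_landmark_csv(resolve(row$tracks_b), fs = cfg$fs)
      analyze_trial(dlt_a, dlt_b, ta, tb,
                    handedness = row$handedness,
                    cutoff_hz = cfg$filter$cutoff_hz,
                    filter_order = cfg$filter$order,
                    ball_radius_m = cfg$release$ball_radius_m,
                    margin_m = cfg$release$margin_m,
                    hold_frames = cfg$release$hold_frames,
                    confidence_threshold = cfg$reconstruction$confidence_threshold,
                    max_gap = cfg$reconstruction$max_gap,
                    window_ms = cfg$window_ms)
    }, pitchpri_error = function(e) {
      status <<- "excluded"
      reason <<- conditionMessage(e)
      NULL
    })
    log_rows[[i]] <- data.frame(pitcher = row$pitcher, trial = row$trial,
                                status = status, reason = reason)
    if (is.null(trial)) next
    trials_by_pitcher[[row$pitcher]] <-
      c(trials_by_pitcher[[row$pitcher]], list(trial))
    rp <- trial$release_params
    trial_rows[[length(trial_rows) + 1]] <- data.frame(
      pitcher = row$pitcher, trial = row$trial, handedness = row$handedness,
      mirror_applied = trial$mirror_applied,
      speed_ms = rp$speed, theta1_deg = rp$theta1_deg,
      theta2_deg = rp$theta2_deg,
      x_m = rp$release_pos[1], y_m = rp$release_pos[2],
      z_m = rp$release_pos[3])
    for (f in c("index", "middle")) {
      pri_rows[[length(pri_rows) + 1]] <- data.frame(
        pitcher = row$pitcher, trial = row$trial, finger = f,
        time_ms = trial$pri$time_ms,
        x_m = trial$pri$series[[f]][, "x"],
        y_m = trial$pri$series[[f]][, "y"],
        z_m = trial$pri$series[[f]][, "z"])
    }
    lmk <- tryCatch(detect_landmarks(trial$az_ms, cfg$window_ms),
                    pitchpri_error = function(e) NULL)
    lm_rows[[length(lm_rows) + 1]] <- data.frame(
      pitcher = row$pitcher, trial = row$trial,
      t_up_peak_ms = if (is.null(lmk)) NA_real_ else lmk$t_up_peak_ms,
      t_zero_cross_ms = if (is.null(lmk)) NA_real_ else lmk$t_zero_cross_ms,
      t_down_peak_ms = if (is.null(lmk)) NA_real_ else lmk$t_down_peak_ms,
      a_up_ms2 = if (is.null(lmk)) NA_real_ else lmk$a_up_ms2,
      a_down_ms2 = if (is.null(lmk)) NA_real_ else lmk$a_down_ms2,
      valid = !is.null(lmk))
    if (!is.null(lmk)) {
      lms_by_pitcher[[row$pitcher]] <- c(lms_by_pitcher[[row$pitcher]],
                                         list(lmk))
    }
  }

  run_log <- do.call(rbind, log_rows)
  usable <- names(trials_by_pitcher)[
    vapply(trials_by_pitcher, length, integer(1)) >= 2]
  if (length(usable) < 3) {
    ppr_stop("config",
             "cohort below minimum: %d pitchers with >= 2 accepted trials (need 3); %d of %d trials excluded",
             length(usable), sum(run_log$status == "excluded"), nrow(run_log))
  }
  aggregates <- lapply(usable, function(p) {
    aggregate_trials(trials_by_pitcher[[p]], pitcher = p)
  })
  names(aggregates) <- usable
  scan <- correlation_scan(aggregates)
  windows <- significant_windows(scan, cfg$alpha)
  summary_tbl <- summarize_release_parameters(aggregates)
  all_lms <- unlist(lms_by_pitcher, recursive = FALSE)
  landmark_summary <- if (length(all_lms) >= 2) summarize_landmarks(all_lms)
                      else NULL

  out <- cfg$paths$output_dir
  write.csv(do.call(rbind, trial_rows),
            file.path(out, "release_parameters.csv"), row.names = FALSE)
  write.csv(do.call(rbind, pri_rows), file.path(out, "pri.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, lm_rows), file.path(out, "landmarks.csv"),
            row.names = FALSE)
  write.csv(summary_tbl, file.path(out, "summary.csv"), row.names = FALSE)
  scan_out <- scan
  scan_out$significant <- scan_out$p < cfg$alpha
  write.csv(scan_out, file.path(out, "scan.csv"), row.names = FALSE)
  write.csv(windows, file.path(out, "windows.csv"), row.names = FALSE)
  log_obj <- list(
    package_version = as.character(utils::packageVersion("pitchpri")),
    config_hash = config_hash(cfg[setdiff(names(cfg), "paths")]),
    n_trials = nrow(run_log),
    n_accepted = sum(run_log$status == "accepted"),
    n_excluded = sum(run_log$status == "excluded"),
    trials = run_log
  )
  jsonlite::write_json(log_obj, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(aggregates = aggregates, scan = scan, windows = windows,
                 summary = summary_tbl, landmark_summary = landmark_summary,
                 log = run_log))
}
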