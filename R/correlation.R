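# Across-trial aggregation per pitcher and the time-resolved across-pitcher
# Pearson correlation scan against release-angle variability.

#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson r with the p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with
#' n - 2 degrees of freedom, two-tailed.
#'
#' @param xs,ys Equal-length numeric vectors, n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r_p <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  n <- length(xs)
  if (length(ys) != n || n < 3) {
    ppr_stop("invalid_argument", "need equal-length vectors with n >= 3")
  }
  stopifnot_finite(xs, "xs"); stopifnot_finite(ys, "ys")
  dx <- xs - mean(xs); dy <- ys - mean(ys)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    ppr_stop("undefined_correlation", "zero variance in one of the inputs")
  }
  r <- sum(dx * dy) / (sx * sy)
  r <- max(min(r, 1), -1)
  list(r = r, p = pearson_p_from_r(r, n), n = n)
}

#' Two-tailed p-value of a Pearson r at sample size n
#'
#' @param r Correlation coefficient(s).
#' @param n Sample size (number of pitchers).
#' @return p-value(s) in `[0, 1]`.
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3) ppr_stop("invalid_argument", "n must be >= 3")
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Critical |r| for two-tailed significance
#'
#' @param n Sample size.
#' @param alpha Significance level (default 0.05).
#' @return The smallest |r| significant at `alpha` (e.g. 0.5324 for n = 14).
#' @export
critical_r <- function(n, alpha = 0.05) {
  tq <- qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Aggregate the trials of one pitcher
#'
#' Across-trial means and sample SDs (n-1 denominator) of the release
#' parameters, and per-millisecond mean and SD of the PRI components for
#' each finger over the release-locked window. All trials must already share
#' the right-handed convention (see [mirror_for_handedness()]).
#'
#' @param trials List of `trial_kinematics` for one pitcher (>= 2).
#' @param pitcher Pitcher identifier carried into the output.
#' @return Object of class `pitcher_aggregate`: `release` (data.frame of
#'   mean/sd per parameter), `sd_theta1_deg`, `sd_theta2_deg`, `pri_mean`
#'   and `pri_sd` (arrays time x finger x component), `az_mean_ms2`,
#'   `time_ms`, `n_trials`.
#' @export
aggregate_trials <- function(trials, pitcher = "P") {
  if (length(trials) < 2) {
    ppr_stop("insufficient_trials", "need at least 2 trials, got %d",
             length(trials))
  }
  mirrored_left <- vapply(trials, function(tr) {
    tr$handedness == "left" && !isTRUE(tr$mirror_applied)
  }, logical(1))
  if (any(mirrored_left)) {
    ppr_stop("invalid_metadata",
             "left-handed trials must be mirrored before aggregation")
  }
  params <- vapply(trials, function(tr) {
    c(speed = tr$release_params$speed,
      theta1_deg = tr$release_params$theta1_deg,
      theta2_deg = tr$release_params$theta2_deg,
      x = unname(tr$release_params$release_pos[1]),
      y = unname(tr$release_params$release_pos[2]),
      z = unname(tr$release_params$release_pos[3]))
  }, numeric(6))
  release <- data.frame(
    parameter = rownames(params),
    mean = apply(params, 1, mean),
    sd = apply(params, 1, sd),
    row.names = NULL
  )
  time_ms <- trials[[1]]$pri$time_ms
  nt <- length(time_ms)
  fingers <- c("index", "middle")
  pri_arr <- array(NA_real_,
                   dim = c(nt, 2, 3, length(trials)),
                   dimnames = list(NULL, fingers, c("x", "y", "z"), NULL))
  for (k in seq_along(trials)) {
    for (f in fingers) pri_arr[, f, , k] <- trials[[k]]$pri$series[[f]]
  }
  az_mat <- vapply(trials, `[[`, numeric(nt), "az_ms")
  structure(list(
    pitcher = pitcher,
    n_trials = length(trials),
    release = release,
    sd_theta1_deg = release$sd[release$parameter == "theta1_deg"],
    sd_theta2_deg = release$sd[release$parameter == "theta2_deg"],
    pri_mean = apply(pri_arr, c(1, 2, 3), mean),
    pri_sd = apply(pri_arr, c(1, 2, 3), sd),
    az_mean_ms2 = rowMeans(az_mat),
    time_ms = time_ms
  ), class = "pitcher_aggregate")
}

#' @export
print.pitcher_aggregate <- function(x, ...) {
  cat(sprintf("<pitcher_aggregate> %s: %d trials, SDtheta1 %.2f deg, SDtheta2 %.2f deg\n",
              x$pitcher, x$n_trials, x$sd_theta1_deg, x$sd_theta2_deg))
  invisible(x)
}

#' Time-resolved across-pitcher correlation scan
#'
#' For every integer millisecond of the release-locked window and every
#' pairing of a per-pitcher PRI statistic (per-ms mean or SD of the x or z
#' component, index or middle finger) with a release-angle variability
#' (SDtheta1 or SDtheta2), computes the across-pitcher Pearson r and
#' two-tailed p. No multiple-testing correction is applied by default (raw
#' per-time-point p); set `p_adjust = "BH"` for a Benjamini-Hochberg
#' variant.
#'
#' @param aggregates List of `pitcher_aggregate` (>= 3 pitchers).
#' @param fingers,components Subsets to scan (defaults: both fingers, x and
#'   z components).
#' @param p_adjust Multiplicity correction across time points within each
#'   pairing, as in [stats::p.adjust()] (default `"none"`).
#' @return data.frame of class `correlation_scan`: `time_ms`, `finger`,
#'   `component`, `stat` ("mean"/"sd"), `angle` ("theta1"/"theta2"),
#'   `pairing` (e.g. "Mean_z_x_SDtheta1" for middle finger), `r`, `r2`,
#'   `p`, `n`.
#' @export
correlation_scan <- function(aggregates, fingers = c("index", "middle"),
                             components = c("x", "z"), p_adjust = "none") {
  if (length(aggregates) < 3) {
    ppr_stop("insufficient_trials", "need at least 3 pitchers, got %d",
             length(aggregates))
  }
  time_ms <- aggregates[[1]]$time_ms
  sd1 <- vapply(aggregates, `[[`, numeric(1), "sd_theta1_deg")
  sd2 <- vapply(aggregates, `[[`, numeric(1), "sd_theta2_deg")
  rows <- list()
  for (f in fingers) for (comp in components) for (st in c("mean", "sd")) {
    field <- if (st == "mean") "pri_mean" else "pri_sd"
    # time x pitcher matrix of the chosen PRI statistic
    mat <- vapply(aggregates, function(a) a[[field]][, f, comp],
                  numeric(length(time_ms)))
    for (ang in c("theta1", "theta2")) {
      y <- if (ang == "theta1") sd1 else sd2
      res <- apply(mat, 1, function(xs) {
        out <- pearson_r_p(xs, y)
        c(out$r, out$p)
      })
      rows[[length(rows) + 1]] <- data.frame(
        time_ms = time_ms, finger = f, component = comp, stat = st,
        angle = ang,
        pairing = scan_pairing_label(f, comp, st, ang),
        r = res[1, ], r2 = res[1, ]^2, p = res[2, ],
        n = length(aggregates)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p <- ave(out$p, out$pairing,
                 FUN = function(p) stats::p.adjust(p, method = p_adjust))
  }
  rownames(out) <- NULL
  class(out) <- c("correlation_scan", "data.frame")
  out
}

scan_pairing_label <- function(finger, component, stat, angle) {
  sprintf("%s_%s_%s_x_SD%s",
          ifelse(stat == "mean", "Mean", "SD"), component, finger, angle)
}

#' Contiguous significant time windows of a correlation scan
#'
#' @param scan A `correlation_scan` data.frame (or any data.frame with
#'   columns `pairing`, `time_ms`, `p`).
#' @param alpha Per-time-point significance level (default 0.05).
#' @return data.frame with one row per maximal contiguous run of significant
#'   time points: `pairing`, `start_ms`, `end_ms`, `n_points`.
#' @export
significant_windows <- function(scan, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    ppr_stop("invalid_argument", "alpha must be in (0, 1)")
  }
  out <- list()
  for (pg in unique(scan$pairing)) {
    sub <- scan[scan$pairing == pg, , drop = FALSE]
    sub <- sub[order(sub$time_ms), , drop = FALSE]
    sig <- sub$p < alpha
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        pairing = pg,
        start_ms = sub$time_ms[starts[k]],
        end_ms = sub$time_ms[ends[k]],
        n_points = r$lengths[k]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(pairing = character(), start_ms = numeric(),
                      end_ms = numeric(), n_points = integer()))
  }
  do.call(rbind, out)
}

#' Cohort release-parameter summary table
#'
#' Per-pitcher mean and SD rows for each release parameter plus an overall
#' row: the mean and sample SD (n-1) of the per-pitcher means, following the
#' per-pitcher columns exactly as given (left-handers are expected to be
#' mirrored upstream).
#'
#' @param per_pitcher Either a list of `pitcher_aggregate` or a data.frame
#'   with columns `pitcher`, then `<param>_mean` / `<param>_sd` for
#'   parameters speed, theta1_deg, theta2_deg, x, y, z.
#' @return data.frame in the same wide format with a final row
#'   `pitcher = "Mean"` holding the across-pitcher mean and SD of the
#'   per-pitcher means.
#' @export
summarize_release_parameters <- function(per_pitcher) {
  params <- c("speed", "theta1_deg", "theta2_deg", "x", "y", "z")
  if (is.data.frame(per_pitcher)) {
    df <- per_pitcher
    need <- c("pitcher", paste0(rep(params, each = 2), c("_mean", "_sd")))
    if (!all(need %in% names(df))) {
      ppr_stop("invalid_argument", "missing columns: %s",
               paste(setdiff(need, names(df)), collapse = ", "))
    }
  } else {
    if (length(per_pitcher) < 2) {
      ppr_stop("insufficient_trials", "need at least 2 pitchers")
    }
    df <- do.call(rbind, lapply(per_pitcher, function(a) {
      row <- data.frame(pitcher = a$pitcher)
      for (p in params) {
        row[[paste0(p, "_mean")]] <- a$release$mean[a$release$parameter == p]
        row[[paste0(p, "_sd")]] <- a$release$sd[a$release$parameter == p]
      }
      row
    }))
  }
  if (nrow(df) < 2) ppr_stop("insufficient_trials", "need at least 2 pitchers")
  overall <- df[1, , drop = FALSE]
  overall[1, ] <- NA
  overall$pitcher <- "Mean"
  for (p in params) {
    overall[[paste0(p, "_mean")]] <- mean(df[[paste0(p, "_mean")]])
    overall[[paste0(p, "_sd")]] <- sd(df[[paste0(p, "_mean")]])
  }
  out <- rbind(df, overall)
  rownames(out) <- NULL
  out
}
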