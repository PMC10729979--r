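# Zero-phase Butterworth filtering and numerical differentiation.
#
# "Fourth-order zero-phase" follows the biomechanics convention: a
# second-order Butterworth passed forward and backward (net fourth order),
# with the design cutoff raised so that the -3 dB point of the dual pass
# lands at the requested cutoff. The correction is applied on the prewarped
# (tan) frequency axis so it is exact for the bilinear-transform digital
# filter, not just the analog prototype.

dual_pass_design_cutoff <- function(cutoff_hz, fs, pass_order, n_passes = 2) {
  if (n_passes == 1) return(cutoff_hz)
  # net |H|^(2 n_passes) at fc must be 1/2  =>  per-pass (f/fd)^(2n) = 2^(1/np)-1
  shrink <- (2^(1 / n_passes) - 1)^(1 / (2 * pass_order))
  warped <- tan(pi * cutoff_hz / fs) / shrink
  atan(warped) * fs / pi
}

# Odd (point-symmetric) reflection padding: continues the series through each
# endpoint, preserving level and slope, so ramps survive the filter edges.
# Operates on columns of a matrix.
reflect_pad <- function(x, np) {
  n <- nrow(x)
  np <- min(np, n - 1)
  head_pad <- matrix(rep(2 * x[1, ], each = np), np) - x[seq(np + 1, 2), , drop = FALSE]
  tail_pad <- matrix(rep(2 * x[n, ], each = np), np) - x[seq(n - 1, n - np), , drop = FALSE]
  rbind(head_pad, x, tail_pad)
}

# IIR filter (direct form II transposed) applied down the rows of a matrix,
# vectorized across columns; identical difference equation to
# signal::filter(), but one R-level loop over time instead of one call per
# series, which matters when filtering thousands of short trajectories.
iir_filter_matrix <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(a) - 1
  nr <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nr, nc)
  Z <- matrix(0, n, nc)
  for (t in seq_len(nr)) {
    xt <- x[t, ]
    yt <- b[1] * xt + Z[1, ]
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        Z[k, ] <- b[k + 1] * xt + Z[k + 1, ] - a[k + 1] * yt
      }
    }
    Z[n, ] <- b[n + 1] * xt - a[n + 1] * yt
    y[t, ] <- yt
  }
  y
}

#' Low-pass Butterworth filter (zero-phase by default)
#'
#' Filters a uniformly sampled series (or each column of a matrix) with a
#' digital Butterworth low-pass. With `zero_phase = TRUE` (the default) the
#' filter is applied forward and backward as two passes of a half-order
#' filter, so the net order equals `order`, the phase is exactly zero, and
#' the design cutoff is corrected so that the net -3 dB point sits at
#' `cutoff_hz`. The series is extended by odd reflection before filtering to
#' suppress edge transients, which matters because the release event sits
#' near the end of a trial.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Desired net -3 dB cutoff (default 60 Hz).
#' @param order Net filter order, even (default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @param literal_order If `TRUE`, run the full `order` in each pass (net
#'   `2 * order`); sensitivity-check variant, default `FALSE`.
#' @return Filtered series, same shape as `x`.
#' @export
butter_lowpass <- function(x, fs, cutoff_hz = 60, order = 4,
                           zero_phase = TRUE, literal_order = FALSE) {
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, ncol = 1)
  stopifnot_finite(x, "series")
  if (fs <= 0) ppr_stop("invalid_spec", "fs must be positive")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    ppr_stop("invalid_spec",
             "cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)", cutoff_hz, fs / 2)
  }
  n <- nrow(x)
  impulse_len <- ceiling(fs / cutoff_hz)
  if (n < max(9, 3 * impulse_len)) {
    ppr_stop("insufficient_data",
             "series of length %d is too short for a %g Hz cutoff at %g Hz sampling",
             n, cutoff_hz, fs)
  }
  np <- min(3 * impulse_len, n - 1)
  # beyond the reflection padding, constant warm-up blocks let the filter
  # state converge to steady state before real data is reached, so constant
  # inputs pass through at machine precision
  warm <- max(np, 48)
  extend <- function(m) {
    rbind(matrix(rep(m[1, ], each = warm), warm), m,
          matrix(rep(m[nrow(m), ], each = warm), warm))
  }
  trim <- function(m) m[warm + np + seq_len(n), , drop = FALSE]
  if (!zero_phase) {
    bf <- signal::butter(order, 2 * cutoff_hz / fs, type = "low")
    y <- iir_filter_matrix(bf$b, bf$a, extend(reflect_pad(x, np)))
    return(if (vec_in) as.numeric(trim(y)) else trim(y))
  }
  if (order %% 2 != 0) {
    ppr_stop("invalid_spec", "zero-phase net order must be even")
  }
  pass_order <- if (literal_order) order else order / 2
  fd <- dual_pass_design_cutoff(cutoff_hz, fs, pass_order)
  bf <- signal::butter(pass_order, 2 * fd / fs, type = "low")
  y <- iir_filter_matrix(bf$b, bf$a, extend(reflect_pad(x, np)))
  y <- iir_filter_matrix(bf$b, bf$a, y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- trim(y[rev(seq_len(nrow(y))), , drop = FALSE])
  if (vec_in) as.numeric(y) else y
}

#' Winter-style residual analysis for cutoff selection
#'
#' Computes the RMS residual between the raw and low-pass-filtered series
#' over a range of candidate cutoffs, fits a straight line to the
#' high-cutoff (noise-dominated) tail of the residual curve, and recommends
#' the lowest cutoff whose residual lies within one noise intercept of that
#' line. The intercept estimates the white-noise contribution to the
#' residual at zero cutoff.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cutoffs_hz At least 5 candidate cutoffs spanning the signal band
#'   and the noise-dominated region above it.
#' @param order,zero_phase Passed to [butter_lowpass()].
#' @return List with `recommended_cutoff_hz`, `residuals` (data.frame of
#'   cutoff_hz, rms), `noise_intercept`, `slope`.
#' @export
residual_analysis <- function(x, fs, cutoffs_hz, order = 4, zero_phase = TRUE) {
  cutoffs_hz <- sort(unique(as.numeric(cutoffs_hz)))
  m <- length(cutoffs_hz)
  if (m < 5) {
    ppr_stop("invalid_argument", "at least 5 candidate cutoffs required")
  }
  rms <- vapply(cutoffs_hz, function(fc) {
    sqrt(mean((x - butter_lowpass(x, fs, fc, order, zero_phase))^2))
  }, numeric(1))
  curve <- data.frame(cutoff_hz = cutoffs_hz, rms = rms)

  if (max(rms) < 1e-12) {
    # effectively nothing removed anywhere: pick the lowest candidate
    return(list(recommended_cutoff_hz = cutoffs_hz[1], residuals = curve,
                noise_intercept = 0, slope = 0))
  }
  if (rms[m] > 0.8 * rms[1]) {
    ppr_stop("analysis_failed",
             "residuals do not decay over the candidate range; candidates do not reach the noise-dominated region")
  }
  k <- max(3, ceiling(0.4 * m))
  tail_idx <- seq(m - k + 1, m)
  tr <- rms[tail_idx]; tc <- cutoffs_hz[tail_idx]
  if (sd(tr) < 1e-12) {
    b0 <- mean(tr); b1 <- 0
  } else {
    fit <- lm(tr ~ tc)
    b0 <- coef(fit)[[1]]; b1 <- coef(fit)[[2]]
    r2 <- summary(fit)$r.squared
    if (b1 > 0 || (r2 < 0.5 && diff(range(tr)) > 1e-9 * max(rms))) {
      ppr_stop("analysis_failed",
               "high-cutoff residual tail is non-monotone; cannot fit a noise line")
    }
    if (b0 < 0) b0 <- 0
  }
  # residuals within one noise intercept of the fitted line are
  # noise-consistent; the 0.5%-of-signal-SD term absorbs the finite rolloff
  # of a realizable filter, which never passes the signal band exactly
  threshold <- b0 + b1 * cutoffs_hz + b0 + 0.005 * sd(x)
  ok <- which(rms <= threshold)
  if (!length(ok)) {
    ppr_stop("analysis_failed", "no candidate cutoff reaches the noise line")
  }
  list(recommended_cutoff_hz = cutoffs_hz[min(ok)], residuals = curve,
       noise_intercept = unname(b0), slope = unname(b1))
}

#' Differentiate a uniformly sampled series
#'
#' Second-order finite differences: central differences at interior samples
#' and one-sided three-point differences at the endpoints (exact for
#' quadratics). Velocity comes from differentiating filtered position, and
#' acceleration from differentiating velocity.
#'
#' @param x Numeric vector or matrix (columns differentiated independently).
#' @param fs Sampling rate in Hz.
#' @return Derivative series, same shape, units of `x` per second.
#' @export
differentiate <- function(x, fs) {
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 3) ppr_stop("insufficient_data", "need at least 3 samples")
  stopifnot_finite(x, "series")
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) * (fs / 2)
  d[1, ] <- (-3 * x[1, ] + 4 * x[2, ] - x[3, ]) * (fs / 2)
  d[n, ] <- (3 * x[n, ] - 4 * x[n - 1, ] + x[n - 2, ]) * (fs / 2)
  if (vec_in) as.numeric(d) else d
}
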