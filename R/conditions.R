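# Classed conditions so callers (and the pipeline's trial-exclusion logic)
# can distinguish failure modes without parsing messages.

ppr_stop <- function(class, msg, ..., data = NULL) {
  cond <- structure(
    class = c(paste0("pitchpri_", class), "pitchpri_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

ppr_warn <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("pitchpri_", class), "pitchpri_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  warning(cond)
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    ppr_stop("invalid_argument", "%s must be finite numeric values", what)
  }
  invisible(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))
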