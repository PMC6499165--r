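# Classed conditions so callers can distinguish contract violations
# (schema problems, degenerate geometry, ...) from ordinary errors.

stop_mm <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "motormap_error"), call = call))
}

#' @keywords internal
assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_mm("value_error", sprintf("%s must be finite (no NA/NaN/Inf)", what))
  }
  invisible(x)
}
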