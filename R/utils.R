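# Internal helpers shared across modules.

# Classed conditions so callers can distinguish failure modes programmatically.
# Classes used: ftirfp_parse_error, ftirfp_format_error, ftirfp_validation_error,
# ftirfp_range_error, ftirfp_degenerate_error, ftirfp_no_peak_error,
# ftirfp_unsupported_error, ftirfp_io_error, ftirfp_config_error.
abort <- function(class, msg) {
  stop(structure(
    class = c(class, "ftirfp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_uniform_grid <- function(x, rel_tol = 1e-6) {
  d <- diff(x)
  h <- stats::median(d)
  all(abs(d - h) <= rel_tol * abs(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
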