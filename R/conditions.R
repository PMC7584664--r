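# Structured error conditions shared across the package.

stop_enstime <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "enstime_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

stop_invalid <- function(message, ...) {
  stop_enstime("enstime_invalid_input", message, ...)
}

stop_degenerate <- function(message, ...) {
  stop_enstime("enstime_degenerate_data", message, ...)
}

stop_fit_failure <- function(message, ...) {
  stop_enstime("enstime_fit_failure", message, ...)
}

stop_numerical <- function(message, ...) {
  stop_enstime("enstime_numerical_failure", message, ...)
}
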