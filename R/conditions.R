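#' @keywords internal
#' Condition helpers
#'
#' All user-facing failures are classed conditions so callers (and the CLI,
#' which maps classes to exit codes) can distinguish parameter errors, data
#' errors, statistical errors and I/O errors.
#' @name qpianiso-conditions
NULL

qpi_stop <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "qpianiso_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

stop_parameter <- function(message, ...) {
  qpi_stop(message, "qpianiso_error_parameter", call = sys.call(-1), ...)
}

stop_data <- function(message, ...) {
  qpi_stop(message, "qpianiso_error_data", call = sys.call(-1), ...)
}

stop_stat <- function(message, ...) {
  qpi_stop(message, "qpianiso_error_stat", call = sys.call(-1), ...)
}

stop_io <- function(message, ...) {
  qpi_stop(message, "qpianiso_error_io", call = sys.call(-1), ...)
}

## distinct class: zero phase variance makes g undefined, which is not the
## same failure as a malformed argument
stop_undefined_anisotropy <- function(message, ...) {
  qpi_stop(message, c("qpianiso_error_undefined_anisotropy",
                      "qpianiso_error_data"), call = sys.call(-1), ...)
}

stop_unscorable <- function(message, missing_fields, ...) {
  qpi_stop(message, c("qpianiso_error_unscorable", "qpianiso_error_data"),
           call = sys.call(-1), missing_fields = missing_fields, ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_parameter(sprintf("`%s` must be provided", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_parameter(sprintf("`%s` must be a single finite number", name))
  if (strict_lower) {
    if (x <= lower)
      stop_parameter(sprintf("`%s` must be > %g (got %g)", name, lower, x))
  } else if (x < lower) {
    stop_parameter(sprintf("`%s` must be >= %g (got %g)", name, lower, x))
  }
  if (x > upper)
    stop_parameter(sprintf("`%s` must be <= %g (got %g)", name, upper, x))
  invisible(x)
}
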