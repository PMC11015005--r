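#' @keywords internal
#' @noRd
abort <- function(msg, class) {
  stop(structure(class = c(class, "harssl_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_format <- function(msg) abort(msg, "harssl_format_error")
stop_data <- function(msg) abort(msg, "harssl_data_error")
stop_param <- function(msg) abort(msg, "harssl_parameter_error")
stop_shape <- function(msg) abort(msg, "harssl_shape_error")
stop_config <- function(msg) abort(msg, "harssl_config_error")
stop_version <- function(msg) abort(msg, "harssl_version_error")
stop_insufficient <- function(msg) abort(msg, "harssl_insufficient_data_error")

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
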