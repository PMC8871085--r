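# Structured error conditions. Every user-facing failure carries a condition
# class so callers (and the CLI) can dispatch without parsing messages.

ck_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "clipkeep_error")))
}

stop_input       <- function(msg, ...) ck_stop("clipkeep_input_error", msg, ...)
stop_format      <- function(msg, ...) ck_stop("clipkeep_format_error", msg, ...)
stop_io          <- function(msg, ...) ck_stop("clipkeep_io_error", msg, ...)
stop_registration <- function(msg, ...) ck_stop("clipkeep_registration_error", msg, ...)
stop_degenerate  <- function(msg, ...) ck_stop("clipkeep_degenerate_histogram_error", msg, ...)
stop_undefined_metric <- function(msg, ...) ck_stop("clipkeep_undefined_metric_error", msg, ...)
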