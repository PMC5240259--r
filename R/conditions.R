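# Structured error conditions. Every user-facing failure carries a subclass of
# "omicstack_error" so callers (and the CLI) can map error classes to behaviour
# without string matching.

stop_omicstack <- function(subclass, message, ...) {
  rlang::abort(message, class = c(subclass, "omicstack_error"), ...)
}

stop_key_error <- function(message) stop_omicstack("omicstack_key_error", message)
stop_validation <- function(message) stop_omicstack("omicstack_validation_error", message)
stop_schema <- function(message) stop_omicstack("omicstack_schema_error", message)
stop_domain <- function(message) stop_omicstack("omicstack_domain_error", message)
stop_conflict <- function(message) stop_omicstack("omicstack_conflict_error", message)
stop_parse <- function(message) stop_omicstack("omicstack_parse_error", message)
stop_format <- function(message) stop_omicstack("omicstack_format_error", message)
stop_config <- function(message) stop_omicstack("omicstack_config_error", message)
stop_insufficient_data <- function(message) stop_omicstack("omicstack_insufficient_data_error", message)
stop_spec <- function(message) stop_omicstack("omicstack_spec_error", message)
stop_usage <- function(message) stop_omicstack("omicstack_usage_error", message)
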