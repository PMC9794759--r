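# Classed conditions so callers (and the CLI) can distinguish bad input
# from internal failure.

oct_stop <- function(message, class) {
  cnd <- structure(
    list(message = message, call = sys.call(-1)),
    class = unique(c(class, "octplaq_input_error", "octplaq_error",
                     "error", "condition")))
  stop(cnd)
}

oct_config_error <- function(message) oct_stop(message, "octplaq_config_error")
oct_schema_error <- function(message) oct_stop(message, "octplaq_schema_error")
oct_annotation_error <- function(message) oct_stop(message, "octplaq_annotation_error")
oct_value_error <- function(message) oct_stop(message, "octplaq_value_error")

oct_log <- function(quiet, ...) {
  if (!isTRUE(quiet)) message("[octplaq] ", ...)
  invisible(NULL)
}
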