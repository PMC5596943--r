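# Classed conditions so callers (and the CLI) can distinguish failure modes.

stop_stratkit <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "stratkit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_stratkit <- function(class, message) {
  warning(structure(
    class = c(class, "stratkit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @keywords internal
stop_param <- function(message) stop_stratkit("param_error", message)
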