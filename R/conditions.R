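# Classed conditions so callers (and the CLI) can distinguish user/config
# mistakes from data problems.

stop_affect <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "affectmove_error")))
}

stop_config <- function(msg, ...) {
  stop_affect("affectmove_config_error", msg, ...)
}

stop_data <- function(msg, ...) {
  stop_affect("affectmove_data_error", msg, ...)
}
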