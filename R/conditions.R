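# Classed conditions so callers (and the CLI) can map failures to exit codes:
# invalid input / validation -> 2, configuration -> 3.

abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("wagglemap_invalid_input", "wagglemap_error")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("wagglemap_validation_error",
                                     "wagglemap_invalid_input", "wagglemap_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("wagglemap_config_error", "wagglemap_error")))
}
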