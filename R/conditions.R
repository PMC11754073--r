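# Classed conditions so callers (and the command-line driver) can map
# failures onto exit codes: input errors (bad files/data) vs config errors
# (bad parameter values).

stop_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("smarc_input_error", "smarc_error"),
                      call = call))
}

stop_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("smarc_config_error", "smarc_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
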