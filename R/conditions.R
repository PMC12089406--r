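# Classed conditions so callers (and the command-line driver) can map
# failures to stable exit codes: config/validation, input parsing,
# computation.

nac_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nacsel_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

config_error  <- function(msg) nac_abort(msg, "nacsel_config_error")
parse_error   <- function(msg) nac_abort(msg, "nacsel_parse_error")
compute_error <- function(msg) nac_abort(msg, "nacsel_compute_error")
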