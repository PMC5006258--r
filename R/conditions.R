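# Classed error conditions so callers (and the CLI) can map error classes to
# exit codes without string-matching messages.

rar_abort <- function(message, class = "rar_input_error") {
  cond <- structure(
    class = c(class, "rar_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

# exit-code mapping used by the command-line surface
rar_exit_code <- function(cond) {
  if (inherits(cond, "rar_config_error")) return(4L)
  if (inherits(cond, "rar_exhausted_error")) return(3L)
  if (inherits(cond, c("rar_validation_error", "rar_input_error"))) return(2L)
  2L
}
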