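# Classed conditions so callers (and the command-line wrapper) can map
# failure kinds to distinct exit codes: config -> 2, parse -> 3, fit -> 4.

config_error <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("[%s] %s", field, msg)
  stop(structure(
    class = c("cnv_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

parse_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  stop(structure(
    class = c("cnv_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), line = line)
  ))
}

fit_error <- function(msg, diagnostics = NULL) {
  stop(structure(
    class = c("cnv_fit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), diagnostics = diagnostics)
  ))
}

usage_error <- function(msg) {
  stop(structure(
    class = c("cnv_usage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
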