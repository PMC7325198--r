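# Structured conditions: every domain failure signals a classed error so
# callers (and the CLI) can distinguish data problems from usage problems.

xrd_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("xrd_", class), "xrd_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

xrd_warning <- function(class, message) {
  warning(structure(
    class = c(paste0("xrd_", class), "xrd_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
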