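# classed conditions so callers (and the CLI's exit-code mapping) can tell
# usage errors, I/O failures and data-contract violations apart
.hc_stop <- function(msg, kind = c("data", "io", "usage"), call. = FALSE) {
  kind <- match.arg(kind)
  stop(errorCondition(msg,
                      class = c(paste0("histocubes_", kind), "histocubes_error")))
}
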