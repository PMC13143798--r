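# Classed conditions so callers (and the CLI exit-code mapping) can react to
# the kind of failure, not the message text.
#
# volcap_config_error   bad parameters / config files        (CLI exit 2)
# volcap_format_error   malformed input data                 (CLI exit 3)
# volcap_grid_error     broken 10 ms timestamp grid          (CLI exit 3)
# volcap_io_error       unreadable/unwritable paths          (CLI exit 3)
# volcap_numeric_error  degenerate fits / insufficient data  (CLI exit 4)
# volcap_contract_error misuse of a per-cycle operation      (CLI exit 4)

vc_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "volcap_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

vc_assert <- function(ok, message, class = "volcap_config_error") {
  if (!isTRUE(ok)) vc_stop(message, class)
  invisible(TRUE)
}
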