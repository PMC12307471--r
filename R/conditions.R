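# Classed conditions so callers (and the CLI) can distinguish user-input
# problems from internal failures.

serfe_abort <- function(message, class) {
  stop(structure(
    class = c(class, "serfe_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_format     <- function(msg) serfe_abort(msg, "serfe_format_error")
abort_geometry   <- function(msg) serfe_abort(msg, "serfe_geometry_error")
abort_roi        <- function(msg) serfe_abort(msg, "serfe_roi_error")
abort_alignment  <- function(msg) serfe_abort(msg, "serfe_alignment_error")
abort_validation <- function(msg) serfe_abort(msg, "serfe_validation_error")
abort_degenerate <- function(msg) serfe_abort(msg, "serfe_degenerate_error")
abort_io         <- function(msg) serfe_abort(msg, "serfe_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
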