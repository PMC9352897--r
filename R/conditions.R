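# Classed conditions so callers (and tests) can distinguish failure modes
# without matching message text.

stop_ctbca <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ctbca_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

input_format_error <- function(msg) stop_ctbca(msg, "ctbca_input_format_error")
metadata_error     <- function(msg) stop_ctbca(msg, "ctbca_metadata_error")
legend_error       <- function(msg) stop_ctbca(msg, "ctbca_legend_error")
validation_error   <- function(msg) stop_ctbca(msg, "ctbca_validation_error")
geometry_error     <- function(msg) stop_ctbca(msg, "ctbca_geometry_error")
spec_error         <- function(msg) stop_ctbca(msg, "ctbca_spec_error")
degenerate_input_error  <- function(msg) stop_ctbca(msg, "ctbca_degenerate_input_error")
degenerate_sample_error <- function(msg) stop_ctbca(msg, "ctbca_degenerate_sample_error")
unsupported_size_error  <- function(msg) stop_ctbca(msg, "ctbca_unsupported_size_error")
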