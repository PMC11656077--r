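# Classed conditions so callers (and tests) can distinguish failure modes:
#   epr_format_error    - malformed on-disk content (headers, column types)
#   epr_value_error     - well-formed content with an out-of-range value
#   epr_integrity_error - violated structural invariant (duplicates, start>=end)
#   epr_config_error    - infeasible or inconsistent parameters
#   epr_lookup_error    - reference to an unknown sample/region

epr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "epr_error", "error", "condition"),
    list(message = if (length(list(...))) sprintf(msg, ...) else msg,
         call = sys.call(-1))
  ))
}

epr_format_error    <- function(msg, ...) epr_stop("epr_format_error", msg, ...)
epr_value_error     <- function(msg, ...) epr_stop("epr_value_error", msg, ...)
epr_integrity_error <- function(msg, ...) epr_stop("epr_integrity_error", msg, ...)
epr_config_error    <- function(msg, ...) epr_stop("epr_config_error", msg, ...)
epr_lookup_error    <- function(msg, ...) epr_stop("epr_lookup_error", msg, ...)
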