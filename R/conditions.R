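# Classed conditions so callers (and tests) can distinguish failure modes.
# Every error raised by the package carries "omics_error" plus a specific class.

os_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "omics_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

os_argument_error  <- function(msg, ...) os_abort(msg, "omics_argument_error", ...)
os_abstract_error  <- function(msg, ...) os_abort(msg, "omics_abstract_error", ...)
os_schema_error    <- function(msg, ...) os_abort(msg, "omics_schema_error", ...)
os_validation_error <- function(msg, ...) os_abort(msg, "omics_validation_error", ...)
os_integrity_error <- function(msg, ...) os_abort(msg, "omics_integrity_error", ...)
os_duplicate_error <- function(msg, ...) os_abort(msg, "omics_duplicate_error", ...)
os_parse_error     <- function(msg, ...) os_abort(msg, "omics_parse_error", ...)
os_storage_error   <- function(msg, ...) os_abort(msg, "omics_storage_error", ...)
os_not_found_error <- function(msg, ...) os_abort(msg, "omics_not_found_error", ...)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_nonempty_string <- function(x) is_string(x) && nzchar(x)
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == trunc(x)
}
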