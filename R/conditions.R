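# Typed condition helpers.  Every error the package raises carries a class
# of the form "replilife_<kind>_error" (plus "replilife_error") so callers
# and tests can branch on the failure mode rather than on message text.

stop_replilife <- function(kind, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("replilife_", kind, "_error"), "replilife_error"),
    ...
  )
}

stop_separation <- function(message = paste(
  "deaths are perfectly separated in time:",
  "the binomial likelihood is unbounded and (a, b) cannot be estimated"
), ...) stop_replilife("separation", message, ...)

stop_insufficient_data <- function(message, ...) {
  stop_replilife("insufficient_data", message, ...)
}

stop_zero_slope <- function(message = "logit slope a is zero; LD50 and maximum life are undefined") {
  stop_replilife("zero_slope", message)
}

stop_empty_input <- function(message) stop_replilife("empty_input", message)

stop_zero_reference <- function(message = "reference value must be > 0") {
  stop_replilife("zero_reference", message)
}

stop_alphabet <- function(message) stop_replilife("alphabet", message)

stop_missing_sequence <- function(message) {
  stop_replilife("missing_sequence", message)
}

stop_not_in_universe <- function(message) {
  stop_replilife("not_in_universe", message)
}

stop_schema <- function(message, ...) stop_replilife("schema", message, ...)

stop_parse <- function(message, ...) stop_replilife("parse", message, ...)

stop_capacity <- function(message) stop_replilife("capacity", message)
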