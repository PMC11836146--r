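# Condition helpers: every user-facing failure carries a class so callers
# (and the pipeline runner) can react programmatically rather than by
# matching message text.
#   helmstrain_format_error    malformed input file (missing column, bad header)
#   helmstrain_data_error      inconsistent or invalid data values
#   helmstrain_parameter_error invalid argument / configuration value
#   helmstrain_numerical_error numerical failure (instability, degenerate norm)
#   helmstrain_contract_error  operation applied outside its domain

stop_format <- function(message, ...) {
  abort(message, class = c("helmstrain_format_error", "helmstrain_error"), ...)
}

stop_data <- function(message, ...) {
  abort(message, class = c("helmstrain_data_error", "helmstrain_error"), ...)
}

stop_parameter <- function(message, ...) {
  abort(message, class = c("helmstrain_parameter_error", "helmstrain_error"), ...)
}

stop_numerical <- function(message, ...) {
  abort(message, class = c("helmstrain_numerical_error", "helmstrain_error"), ...)
}

stop_contract <- function(message, ...) {
  abort(message, class = c("helmstrain_contract_error", "helmstrain_error"), ...)
}
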