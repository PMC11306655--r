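# Structured conditions so callers (and the CLI wrapper) can map failures to
# exit codes: validation -> 2, I/O -> 3, numerical -> 4.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pdfe_validation_error", "pdfe_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pdfe_io_error", "pdfe_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pdfe_numerical_error", "pdfe_error")))
}
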