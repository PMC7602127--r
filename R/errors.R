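# Condition classes shared across the package.
#
# Three families of failure are distinguished so that callers (and the
# command-line wrapper) can map them onto exit codes:
#   * usage errors      -- bad arguments / unknown options          (exit 1)
#   * validation errors -- inputs violate a documented invariant    (exit 1)
#   * data errors       -- unreadable, garbled or empty input data  (exit 2)

cc_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "chemocomp_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_usage <- function(msg) cc_stop(msg, "chemocomp_usage_error")

stop_validation <- function(msg) cc_stop(msg, "chemocomp_validation_error")

stop_data <- function(msg) cc_stop(msg, "chemocomp_data_error")
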