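# Structured error conditions. Every error raised by the package carries the
# class "myofq_error" plus a specific subclass so callers can branch on the
# failure mode (e.g. a missing ACF minimum is recoverable, a size error is
# not).

myofq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "myofq_error"), call = call))
}

#' @noRd
stop_degenerate <- function(msg) myofq_stop(msg, "myofq_degenerate_input")

#' @noRd
stop_no_minimum <- function(msg) myofq_stop(msg, "myofq_no_minimum")
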