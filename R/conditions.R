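# Structured conditions so callers (and the CLI) can distinguish bad input
# from fits that cannot be computed.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tracern2o_validation_error", "tracern2o_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tracern2o_estimation_error", "tracern2o_error")))
}
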