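# Classed conditions so callers and tests can distinguish bad inputs from
# bad configuration or I/O failures.

abort_invalid_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("histoseg_invalid_input", "histoseg_error"),
                      call = call))
}

abort_invalid_param <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("histoseg_invalid_param", "histoseg_error"),
                      call = call))
}

abort_config <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("histoseg_config_error", "histoseg_error"),
                      call = call))
}

abort_io <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("histoseg_io_error", "histoseg_error"),
                      call = call))
}
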