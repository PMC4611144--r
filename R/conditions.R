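# Structured error conditions so callers (and the CLI) can categorize
# failures into validation / numerical / io without parsing messages.

stop_longvbm <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "longvbm_error"),
                      call = call))
}

stop_validation <- function(msg) stop_longvbm(msg, "longvbm_validation_error")
stop_dimension  <- function(msg) stop_longvbm(msg, c("longvbm_dimension_error",
                                                     "longvbm_validation_error"))
stop_design     <- function(msg) stop_longvbm(msg, c("longvbm_design_error",
                                                     "longvbm_validation_error"))
stop_data       <- function(msg) stop_longvbm(msg, c("longvbm_data_error",
                                                     "longvbm_validation_error"))
stop_numerical  <- function(msg) stop_longvbm(msg, "longvbm_numerical_error")
stop_io         <- function(msg) stop_longvbm(msg, "longvbm_io_error")
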