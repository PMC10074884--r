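# Classed conditions used across the package. Every domain error inherits
# from "codonopt_error" so callers can catch the whole family.

co_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "codonopt_error"),
                      call = call))
}

abort_invalid_cds <- function(msg) co_abort(msg, "codonopt_invalid_cds")
abort_alphabet    <- function(msg) co_abort(msg, "codonopt_alphabet_error")
abort_config      <- function(msg) co_abort(msg, "codonopt_config_error")
abort_parse       <- function(msg) co_abort(msg, "codonopt_parse_error")
abort_data        <- function(msg) co_abort(msg, "codonopt_data_error")
abort_degenerate  <- function(msg) co_abort(msg, "codonopt_degenerate_usage")
abort_undefined   <- function(msg) co_abort(msg, "codonopt_undefined_value")
abort_format      <- function(msg) co_abort(msg, "codonopt_format_error")
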