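# Internal condition helpers. Every user-facing failure carries a condition
# class so callers (and the CLI) can distinguish validation problems from
# degenerate-data problems without parsing messages.

pgain_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "pgain_error"),
                      call = call))
}

# validation of file/table contents and malformed arguments
pgain_validation_error <- function(message, call = sys.call(-1)) {
  pgain_error(message, "pgain_validation_error", call)
}

# mathematically out-of-domain inputs (e.g. p-gain <= 0, q outside (0,1))
pgain_domain_error <- function(message, call = sys.call(-1)) {
  pgain_error(message, "pgain_domain_error", call)
}

# data that defeat the statistic (constant trait, constant quantity, n too
# small, all-tied vectors)
pgain_degenerate_error <- function(message, call = sys.call(-1)) {
  pgain_error(message, "pgain_degenerate_error", call)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
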