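# Classed error conditions so callers (and tests) can distinguish failure
# modes without string-matching messages.
pkg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phbrtmb_error")))
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
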