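#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish configuration, geometry,
# schema and selection failures programmatically.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("locrad_", class), "locrad_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
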