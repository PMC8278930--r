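## internal helpers shared across modules

stopf <- function(fmt, ..., class = "mabtherm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name, class = "mabtherm_validation_error")
  if (positive && x <= 0)
    stopf("'%s' must be > 0 (got %g)", name, x, class = "mabtherm_validation_error")
  invisible(x)
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

## gas constant, J/(mol K)
.R_GAS <- 8.314

celsius_to_kelvin <- function(t_c) t_c + 273.15
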