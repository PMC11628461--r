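# Classed error conditions so callers can distinguish failure modes.

vp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ventpower_error", "error"),
                      call = call))
}

stop_invalid_parameter <- function(msg) {
  vp_stop(msg, "ventpower_invalid_parameter")
}

stop_dead_space_violation <- function(msg) {
  vp_stop(msg, "ventpower_dead_space_violation")
}

stop_degenerate_expiration <- function(msg) {
  vp_stop(msg, "ventpower_degenerate_expiration")
}

stop_no_feasible_point <- function(msg) {
  vp_stop(msg, "ventpower_no_feasible_point")
}

stop_convergence <- function(msg) {
  vp_stop(msg, "ventpower_convergence_error")
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid_parameter(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid_parameter(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_invalid_parameter(sprintf("'%s' must be >= 0 (got %g)", name, x))
  as.numeric(x)  # integers (e.g. from YAML) are promoted to double
}
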