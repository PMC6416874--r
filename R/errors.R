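# Classed conditions so callers (and the CLI) can distinguish bad input from
# numerical failure. All inherit from "jointpwr_error".

stop_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg,
    class = c("jointpwr_input_error", "jointpwr_error")))
}

stop_unsupported <- function(msg) {
  stop(errorCondition(msg,
    class = c("jointpwr_unsupported_error", "jointpwr_error")))
}

stop_convergence <- function(msg) {
  stop(errorCondition(msg,
    class = c("jointpwr_convergence_error", "jointpwr_error")))
}

stop_no_solution <- function(msg) {
  stop(errorCondition(msg,
    class = c("jointpwr_no_solution_error", "jointpwr_error")))
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop_input(sprintf("'%s' must be a single number strictly between 0 and 1", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
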