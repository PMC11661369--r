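# Structured conditions so the CLI can map failures to exit codes.

pf_error <- function(msg, class, call = sys.call(-1), data = NULL) {
  stop(structure(
    class = c(class, "pf_error", "error", "condition"),
    list(message = msg, call = call, data = data)
  ))
}

pf_usage_error <- function(msg, data = NULL) {
  pf_error(msg, "pf_usage_error", call = sys.call(-1), data = data)
}

pf_infeasible_error <- function(msg, data = NULL) {
  pf_error(msg, "pf_infeasible_error", call = sys.call(-1), data = data)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pf_error(sprintf("`%s` must be a single finite number", name), "pf_usage_error")
  if (positive && x <= 0)
    pf_error(sprintf("`%s` must be > 0", name), "pf_usage_error")
  invisible(x)
}
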