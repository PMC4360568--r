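# Structured error conditions. Every user-facing failure carries one of
# three classes so callers (and the CLI dispatcher) can map them to exit
# codes without string-matching messages.

abort_domain <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("mutload_domain_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_contract <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("mutload_contract_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_solver <- function(msg, diagnostics = NULL, call = sys.call(-1)) {
  stop(structure(
    class = c("mutload_solver_error", "error", "condition"),
    list(message = msg, call = call, diagnostics = diagnostics)
  ))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_domain(sprintf("`%s` must be a single non-missing number", name))
  if (x < min || x > max)
    abort_domain(sprintf("`%s` = %g is outside [%g, %g]", name, x, min, max))
  invisible(x)
}
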