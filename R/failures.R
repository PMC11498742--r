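# Structured failure signalling.  Low-level routines signal classed
# conditions; the orchestration layer converts them into (category, phase)
# fields so callers can tabulate failure rates instead of handling raw
# exceptions.

signal_failure <- function(category, message, phase = NA_character_) {
  stop(structure(class = c("eqsens_failure", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      category = category, phase = phase)))
}

signal_tailored_inapplicable <- function(message) {
  stop(structure(class = c("eqsens_tailored_inapplicable", "eqsens_failure",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      category = "tailored_method_inapplicable",
                      phase = NA_character_)))
}

failure_category <- function(cond) {
  if (!is.null(cond$category)) cond$category else "numerical_error"
}

# run code without disturbing the caller's RNG stream
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

# Newton failing on a singular Jacobian is reported as
# tailored_method_inapplicable when the rank deficiency stems from a
# conserved quantity (the model should be reduced first); otherwise it
# stays a numerical error.
classify_ss_failure <- function(model, deriv, res) {
  if (res$status == "numerical_error" &&
      identical(res$reason, "singular_jacobian") &&
      length(with_preserved_rng(
        detect_conservation(model, deriv, seed = 20240101L))))
    return("tailored_method_inapplicable")
  res$status
}
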