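# Shared test helpers: small constructors and canonical solution keys.

lit <- function(name, polarity = "present") state_literal(name, polarity)

# history from character world specs: hw(c("C"), c("C","E"), ...)
hw <- function(...) {
  gubs_history(lapply(list(...), function(w) lapply(w, lit)))
}

# single-rule program kind C -> E over constants
one_rule <- function(kind, cause = "C", effect = "E",
                     effect_polarity = "present") {
  gubs_program(rules = list(causal_rule(
    kind,
    lapply(cause, lit),
    lapply(effect, lit, polarity = effect_polarity))))
}

# canonical (sorted multiset, sigma) key shared by pipeline and oracle
solution_key <- function(tuple, sigma) {
  sig <- if (length(sigma)) {
    o <- order(names(sigma))
    paste(names(sigma)[o], sigma[o], sep = ">", collapse = ";")
  } else ""
  paste(paste(sort(tuple), collapse = ","), sig, sep = "|")
}

pipeline_keys <- function(res)
  sort(vapply(res$solutions, function(r)
    solution_key(r$components, r$substitution$map), ""))

oracle_keys <- function(orc)
  sort(vapply(orc, function(s) solution_key(s$tuple, s$sigma), ""))

eq1_trace <- function() {
  gubs_trace(lapply(c("G(Low)", "G(Low)", "G(Mid)", "G(Mid)", "G(Mid)",
                      "G(High)"), function(t)
    list(gubsc:::parse_literal_token(t))))
}

world_tokens <- function(h)
  lapply(h$worlds, function(w) vapply(w, gubsc:::lit_token, ""))
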