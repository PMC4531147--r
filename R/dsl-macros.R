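# Macro relations.  Strong inhibition a -- b states that a represses b and
# that b recovers when a is gone; strong activation a -+ b is the dual.
# Both are eliminated into pairs of causal primitives:
#
#   a -- b   =>   { a o-> !b ,  !a -> b  }
#   a -+ b   =>   { a o-> b  ,  !a -> !b }
#
# The persistent half records that the repressor (activator) is still
# present while its effect is observed; the normal half records the
# release behaviour.

#' Expand macro relations into causal primitives
#'
#' Replaces every strong-inhibition rule `a -- b` by the pair
#' `{a o-> !b, !a -> b}` and every strong-activation rule `a -+ b` by
#' `{a o-> b, !a -> !b}`; primitive rules pass through unchanged.  The
#' result contains only the three primitive kinds, and the operation is
#' idempotent.
#'
#' @param p A [gubs_program()].
#' @return A [gubs_program()] without macro rules.
#' @export
expand_macros <- function(p) {
  out <- list()
  for (r in p$rules) {
    if (r$kind %in% RULE_KINDS) {
      out <- c(out, list(r))
      next
    }
    a <- r$cause[[1]]
    b <- r$effect[[1]]
    if (r$kind == "strong_inh") {
      out <- c(out,
               list(causal_rule("persistent", list(a),
                                list(negate_literal(b)), r$scope),
                    causal_rule("normal", list(negate_literal(a)),
                                list(b), r$scope)))
    } else {  # strong_act
      out <- c(out,
               list(causal_rule("persistent", list(a), list(b), r$scope),
                    causal_rule("normal", list(negate_literal(a)),
                                list(negate_literal(b)), r$scope)))
    }
  }
  gubs_program(unname(p$declarations), out, unname(p$spots))
}

# substitute variable agents by their images under a named character map
substitute_agent <- function(a, map) {
  if (is_constant_agent(a)) return(a)
  img <- map[[a$name]]
  if (is.null(img) || is.na(img)) a else agent_ref(img)
}

substitute_literal <- function(l, map) {
  l$agent <- substitute_agent(l$agent, map)
  l
}

substitute_rule <- function(r, map) {
  sc <- r$scope
  sc$contexts <- lapply(sc$contexts, substitute_agent, map = map)
  causal_rule(r$kind,
              lapply(r$cause, substitute_literal, map = map),
              lapply(r$effect, substitute_literal, map = map),
              sc)
}

substitute_program <- function(p, map) {
  if (!length(map)) return(p)
  decls <- lapply(unname(p$declarations), function(d) {
    d$agent <- substitute_agent(d$agent, map)
    d
  })
  spots <- lapply(unname(p$spots), function(s) {
    s$observed <- substitute_literal(s$observed, map)
    s
  })
  gubs_program(decls, lapply(p$rules, substitute_rule, map = map), spots)
}
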