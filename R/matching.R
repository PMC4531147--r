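# Conservative pre-selection of component subsets.
#
# Two filters run before ACI-unification: a local causal association
# between each goal rule and the rules of candidate components, and
# occurrence-count constraints on agents.  Both are necessary conditions
# for unification, so they prune without losing solutions: a goal rule
# with an empty association set makes the whole compilation fail, and a
# tuple violating the agent constraints cannot be unified.

# occurrence counts of agents, keyed name/side/polarity, over effective
# rules; each rule side contributes at most one occurrence per literal
occurrence_counts <- function(rules, kind = c("constant", "variable")) {
  kind <- match.arg(kind)
  env <- new.env(parent = emptyenv())
  bump <- function(name, side, pol) {
    k <- paste(name, side, pol, sep = "\r")
    env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + 1L
  }
  for (er in rules) {
    for (l in er$cause)
      if (l$agent$kind == kind) bump(l$agent$name, "cause", l$polarity)
    for (l in er$effect)
      if (l$agent$kind == kind) bump(l$agent$name, "effect", l$polarity)
  }
  keys <- ls(env)
  if (!length(keys))
    return(data.frame(name = character(), side = character(),
                      polarity = character(), count = integer(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(name = parts[, 1], side = parts[, 2], polarity = parts[, 3],
             count = vapply(keys, function(k) env[[k]], 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

count_of <- function(tab, name, side, pol) {
  i <- tab$name == name & tab$side == side & tab$polarity == pol
  if (any(i)) sum(tab$count[i]) else 0L
}

# injective assignment of p-literals to q-literals on one side
side_counterparts_exist <- function(p_lits, q_lits, p_decls, q_decls) {
  np <- length(p_lits)
  if (np > length(q_lits)) return(FALSE)
  compat <- matrix(FALSE, np, length(q_lits))
  for (i in seq_len(np)) {
    lp <- p_lits[[i]]
    for (j in seq_along(q_lits)) {
      lq <- q_lits[[j]]
      ok <- lp$polarity == lq$polarity &&
        (!is_constant_agent(lp$agent) || lp$agent$name == lq$agent$name) &&
        declared_attr_count(lp$agent$name, p_decls) <=
          declared_attr_count(lq$agent$name, q_decls)
      compat[i, j] <- ok
    }
  }
  assign_rec <- function(i, used) {
    if (i > np) return(TRUE)
    for (j in which(compat[i, ] & !used))
      if (assign_rec(i + 1L, `[<-`(used, j, TRUE))) return(TRUE)
    FALSE
  }
  assign_rec(1L, rep(FALSE, length(q_lits)))
}

#' Local causal association between two rules
#'
#' A goal rule `p` associates with a component rule `q` when all five
#' structural conditions hold: same rule kind; every constant of `p`
#' present in `q` on the same side with the same polarity; cause and
#' effect cardinalities of `q` at least those of `p`; an injective
#' counterpart assignment per side preserving the declared attribute
#' order; and each `p`-agent's declared attribute count at most its
#' counterpart's.  Context agents are treated as cause conjuncts and
#' compartment paths must coincide.
#'
#' @param p,q Macro-expanded [causal_rule()]s.
#' @param p_decls,q_decls Declaration lists of the owning programs (for
#'   attribute counts); default empty.
#' @return Logical; on `FALSE` the attribute `reason` names the first
#'   failing condition.
#' @export
rule_associates <- function(p, q, p_decls = list(), q_decls = list()) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (p$kind != q$kind) return(fail("rule kind differs"))
  pe <- effective_rule1(p)
  qe <- effective_rule1(q)
  if (pe$path != qe$path) return(fail("compartment scope differs"))
  if (length(qe$cause) < length(pe$cause) ||
      length(qe$effect) < length(pe$effect))
    return(fail("cardinality of cause/effect too small"))
  for (side in c("cause", "effect")) {
    for (l in pe[[side]]) {
      if (!is_constant_agent(l$agent)) next
      hit <- any(vapply(qe[[side]], function(m)
        m$agent$name == l$agent$name && m$polarity == l$polarity, TRUE))
      if (!hit)
        return(fail(paste0("constant ", l$agent$name, " missing from ",
                           side, " side")))
    }
    if (!side_counterparts_exist(pe[[side]], qe[[side]], p_decls, q_decls))
      return(fail(paste0("no attribute-compatible counterpart assignment on ",
                         side, " side")))
  }
  TRUE
}

#' Associate each goal rule with library components
#'
#' For each rule of the goal, computes the set of (component, rule) pairs
#' that locally associate with it.  A goal rule with an empty set makes
#' ACI-unification fail globally; such rules are flagged.
#'
#' @param goal Macro-expanded [gubs_program()].
#' @param lib A [gubs_library()].
#' @return Object of class `gubs_association`: per goal rule, a data frame
#'   of associating `(component, rule)` pairs, plus the per-rule component
#'   sets and the indices of orphan rules.
#' @export
associate <- function(goal, lib) {
  stopifnot(inherits(lib, "gubs_library"))
  per_rule <- lapply(seq_along(goal$rules), function(i) {
    p <- goal$rules[[i]]
    hits <- list()
    for (cn in names(lib$components)) {
      comp <- lib$components[[cn]]
      for (j in seq_along(comp$rules)) {
        if (isTRUE(rule_associates(p, comp$rules[[j]], goal$declarations,
                                   comp$declarations)))
          hits[[length(hits) + 1L]] <- list(component = cn, rule = j)
      }
    }
    data.frame(component = vapply(hits, `[[`, "", "component"),
               rule = vapply(hits, `[[`, 0L, "rule"),
               stringsAsFactors = FALSE)
  })
  comp_sets <- lapply(per_rule, function(df) unique(df$component))
  orphans <- which(vapply(comp_sets, length, 0L) == 0L)
  structure(list(pairs = per_rule, components = comp_sets,
                 orphans = orphans, goal = goal),
            class = "gubs_association")
}

#' @export
print.gubs_association <- function(x, ...) {
  for (i in seq_along(x$pairs)) {
    cs <- x$components[[i]]
    cat(sprintf("rule %d (%s): %s\n", i, rule_token(x$goal$rules[[i]]),
                if (length(cs)) paste(cs, collapse = ", ") else "<none>"))
  }
  invisible(x)
}

#' Agent occurrence constraints on a candidate tuple
#'
#' Necessary conditions checked before unification, with occurrence counts
#' refined by side (cause vs effect) and polarity: (1) every goal
#' constant's occurrence count must not exceed its count over the tuple's
#' components (duplicated slots count twice); (2) every goal variable
#' needs at least one candidate constant in the tuple that does not occur
#' in the goal, with occurrence counts at least the variable's in every
#' side/polarity combination and a compatible declared attribute count.
#'
#' @param goal Macro-expanded [gubs_program()].
#' @param components List of component [gubs_program()]s (the tuple slots;
#'   repetitions allowed).
#' @return Logical; on `FALSE` the attribute `reason` explains the first
#'   violated constraint.
#' @export
agent_constraints_ok <- function(goal, components) {
  stopifnot(length(components) >= 1L)
  fail <- function(reason) structure(FALSE, reason = reason)
  goal_rules <- effective_rules(goal)
  q_rules <- do.call(c, lapply(components, effective_rules))
  p_const <- occurrence_counts(goal_rules, "constant")
  q_const <- occurrence_counts(q_rules, "constant")
  p_var <- occurrence_counts(goal_rules, "variable")
  goal_constants <- unique(p_const$name)
  # (1) constants of the goal must occur at least as often in the tuple
  for (i in seq_len(nrow(p_const))) {
    need <- p_const$count[i]
    have <- count_of(q_const, p_const$name[i], p_const$side[i],
                     p_const$polarity[i])
    if (have < need)
      return(fail(sprintf(
        "constant %s occurs %d time(s) as %s %s in the goal but %d in the tuple",
        p_const$name[i], need,
        if (p_const$polarity[i] == "absent") "negated" else "positive",
        p_const$side[i], have)))
  }
  # (2) every goal variable needs a fresh candidate constant
  decls_q <- do.call(c, lapply(components, function(cp)
    unname(cp$declarations)))
  if (is.null(decls_q)) decls_q <- list()
  names(decls_q) <- vapply(decls_q, function(d) d$agent$name, "")
  for (v in unique(p_var$name)) {
    vi <- p_var[p_var$name == v, , drop = FALSE]
    candidates <- setdiff(unique(q_const$name), goal_constants)
    ok <- FALSE
    for (cand in candidates) {
      fits <- all(vapply(seq_len(nrow(vi)), function(k)
        count_of(q_const, cand, vi$side[k], vi$polarity[k]) >= vi$count[k],
        TRUE)) &&
        declared_attr_count(v, goal$declarations) <=
          declared_attr_count(cand, decls_q)
      if (fits) { ok <- TRUE; break }
    }
    if (!ok)
      return(fail(sprintf(
        "no fresh constant in the tuple can substitute variable %s", v)))
  }
  TRUE
}

#' Enumerate candidate component tuples
#'
#' Produces, for a goal of n rules, the tuples assigning one associated
#' component to each rule (repetitions allowed: several slots may pick the
#' same component).  Enumeration is deterministic, first slot varying
#' fastest.  Tuples failing [agent_constraints_ok()] are filtered out when
#' `agent_filter` is `TRUE`; the count before filtering and the
#' eliminations (with reasons) are reported.
#'
#' @param goal Macro-expanded [gubs_program()].
#' @param lib A [gubs_library()].
#' @param map An existing [associate()] result (recomputed when `NULL`).
#' @param agent_filter Apply the agent constraints filter.
#' @param max_candidates Guard on the enumeration size.
#' @return List with `tuples` (list of character vectors of component
#'   names), `n_before`, and `eliminated` (tuples with reasons).
#' @export
candidate_subsets <- function(goal, lib, map = NULL, agent_filter = TRUE,
                              max_candidates = 1e5) {
  if (is.null(map)) map <- associate(goal, lib)
  if (length(map$orphans))
    stop("goal rule(s) without any associated component: ",
         paste(vapply(map$orphans, function(i)
           rule_token(goal$rules[[i]]), ""), collapse = "; "),
         call. = FALSE)
  sets <- map$components
  n_before <- prod(vapply(sets, length, 0L))
  if (n_before > max_candidates)
    stop("candidate enumeration too large (", n_before, " tuples)",
         call. = FALSE)
  n_before <- as.integer(n_before)
  effort_bump("tuples", n_before)
  if (!length(goal$rules))
    return(list(tuples = list(character()), n_before = 1L,
                eliminated = list()))
  grid <- expand.grid(sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tuples <- lapply(seq_len(nrow(grid)), function(i)
    unname(unlist(grid[i, ], use.names = FALSE)))
  if (!agent_filter)
    return(list(tuples = tuples, n_before = n_before, eliminated = list()))
  keep <- logical(length(tuples))
  eliminated <- list()
  for (i in seq_along(tuples)) {
    comps <- lapply(tuples[[i]], function(nm) lib$components[[nm]])
    ok <- agent_constraints_ok(goal, comps)
    keep[i] <- isTRUE(ok)
    if (!keep[i])
      eliminated[[length(eliminated) + 1L]] <-
        list(tuple = tuples[[i]], reason = attr(ok, "reason"))
  }
  list(tuples = tuples[keep], n_before = n_before, eliminated = eliminated)
}
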