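# Satisfaction of programs over linear Kripke models, and bounded model
# enumeration for observability, behavioural inclusion and the
# subsumption chain between the three causal primitives.
#
# Worlds are read with a closed-world convention: a present literal holds
# iff the world contains a compatible positive atom; an absent literal
# holds iff it contains none.  The atom alphabet of a check is the set of
# distinct (compartment, agent, qualifier) triples occurring in the
# programs (and model) involved, so bounded enumeration ranges over all
# subsets of that alphabet per world.
#
# Numeric qualifiers: a rule literal with an interval qualifier is
# satisfied by a point atom lying inside it or by an interval atom
# contained in it; a point literal requires the identical point.

# contexts become cause conjuncts; compartments namespace the atoms
effective_rule1 <- function(r) {
  if (r$kind %in% MACRO_KINDS)
    stop("unexpanded macro rule; call expand_macros()", call. = FALSE)
  ctx <- lapply(r$scope$contexts, function(a) state_literal(a))
  list(kind = r$kind,
       cause = canon_lit_set(c(r$cause, ctx)),
       effect = r$effect,
       path = compartment_path(r$scope))
}

effective_rules <- function(p) lapply(p$rules, effective_rule1)

effective_spots <- function(p)
  lapply(unname(p$spots), function(s) list(lit = s$observed, path = ""))

# ---- atom alphabet ----------------------------------------------------------

atom_key <- function(path, name, qual)
  paste(path, name, qual_token(qual), sep = "\r")

# collect distinct atoms from programs (effective form) and model worlds
semantic_atoms <- function(progs = list(), models = list()) {
  seen <- new.env(parent = emptyenv())
  atoms <- list()
  add <- function(path, agent, qual) {
    k <- atom_key(path, agent$name, qual)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      atoms[[length(atoms) + 1L]] <<- list(path = path, name = agent$name,
                                           qual = qual, key = k)
    }
  }
  for (p in progs) {
    for (er in effective_rules(p))
      for (l in c(er$cause, er$effect)) add(er$path, l$agent, l$qualifier)
    for (es in effective_spots(p)) add(es$path, es$lit$agent,
                                       es$lit$qualifier)
  }
  for (m in models)
    for (w in m$worlds)
      for (l in w) if (l$polarity == "present") add("", l$agent, l$qualifier)
  if (length(atoms) > 22L)
    stop("atom alphabet too large for bounded model enumeration (",
         length(atoms), " atoms, maximum 22)", call. = FALSE)
  atoms
}

qual_compatible <- function(rule_q, atom_q) {
  switch(rule_q$type,
         none = TRUE,
         label = atom_q$type == "label" && atom_q$value == rule_q$value,
         point = atom_q$type == "point" && atom_q$value == rule_q$value,
         interval = (atom_q$type == "point" &&
                       atom_q$value >= rule_q$value[1] &&
                       atom_q$value <= rule_q$value[2]) ||
                    (atom_q$type == "interval" &&
                       atom_q$value[1] >= rule_q$value[1] &&
                       atom_q$value[2] <= rule_q$value[2]))
}

compat_mask <- function(lit, path, atoms) {
  m <- 0L
  for (i in seq_along(atoms)) {
    a <- atoms[[i]]
    if (a$path == path && a$name == lit$agent$name &&
        qual_compatible(lit$qualifier, a$qual))
      m <- bitwOr(m, bitwShiftL(1L, i - 1L))
  }
  m
}

# encode one program against an atom alphabet:
#  rules: list of IntegerVector [kind, nc, ne, (mask,pos)*nc, (mask,pos)*ne]
#  spots: list of IntegerVector c(mask, pos)
encode_program <- function(p, atoms) {
  enc_lit <- function(l, path)
    c(compat_mask(l, path, atoms), if (l$polarity == "present") 1L else 0L)
  rules <- lapply(effective_rules(p), function(er) {
    kind <- match(er$kind, RULE_KINDS) - 1L
    as.integer(c(kind, length(er$cause), length(er$effect),
                 unlist(lapply(er$cause, enc_lit, path = er$path)),
                 unlist(lapply(er$effect, enc_lit, path = er$path))))
  })
  spots <- lapply(effective_spots(p), function(es)
    as.integer(enc_lit(es$lit, es$path)))
  list(rules = rules, spots = spots)
}

# a model world -> bitmask over the atom alphabet (positive literals only)
world_masks <- function(model, atoms) {
  keys <- vapply(atoms, `[[`, "", "key")
  vapply(model$worlds, function(w) {
    m <- 0L
    for (l in w) {
      if (l$polarity != "present") next  # absence is the closed-world default
      i <- match(atom_key("", l$agent$name, l$qualifier), keys)
      if (!is.na(i)) m <- bitwOr(m, bitwShiftL(1L, i - 1L))
    }
    m
  }, integer(1))
}

decode_worlds <- function(masks, atoms) {
  lapply(masks, function(m) {
    picked <- atoms[bitwAnd(m, bitwShiftL(1L, seq_along(atoms) - 1L)) != 0L]
    vapply(picked, function(a)
      paste0(if (nzchar(a$path)) paste0(a$path, "::") else "", a$name,
             qual_token(a$qual)), "")
  })
}

# ---- reference satisfaction check in R (the Rcpp kernel mirrors this) -------

lit_holds_r <- function(w, mask, pos)
  if (pos == 1L) bitwAnd(w, mask) != 0L else bitwAnd(w, mask) == 0L

set_holds_r <- function(w, lits)  # lits: matrix with columns mask,pos
  all(vapply(seq_len(nrow(lits)),
             function(i) lit_holds_r(w, lits[i, 1L], lits[i, 2L]), TRUE))

rule_parts <- function(enc) {
  nc <- enc[2L]; ne <- enc[3L]
  list(kind = enc[1L],
       cause = matrix(enc[3L + seq_len(2L * nc)], ncol = 2L, byrow = TRUE),
       effect = matrix(enc[3L + 2L * nc + seq_len(2L * ne)], ncol = 2L,
                       byrow = TRUE))
}

# is rule `enc` violated at world index t of masks?
rule_violated_at_r <- function(masks, t, parts) {
  w <- masks[t]
  for (i in seq_len(nrow(parts$effect))) {
    em <- parts$effect[i, 1L]; ep <- parts$effect[i, 2L]
    if (!lit_holds_r(w, em, ep)) next
    cause_earlier <- t > 1L &&
      any(vapply(seq_len(t - 1L),
                 function(s) set_holds_r(masks[s], parts$cause), TRUE))
    if (parts$kind == 0L) {          # normal: cause strictly earlier
      if (!cause_earlier) return(TRUE)
    } else if (parts$kind == 1L) {   # persistent: also co-present
      if (!cause_earlier || !set_holds_r(w, parts$cause)) return(TRUE)
    } else {                         # remnant
      if (t == 1L) {
        if (!set_holds_r(w, parts$cause)) return(TRUE)
      } else if (!lit_holds_r(masks[t - 1L], em, ep) && !cause_earlier) {
        return(TRUE)
      }
    }
  }
  FALSE
}

check_model_r <- function(masks, rules, spots) {
  rule_ok <- vapply(rules, function(enc) {
    parts <- rule_parts(enc)
    !any(vapply(seq_along(masks),
                function(t) rule_violated_at_r(masks, t, parts), TRUE))
  }, TRUE)
  spot_ok <- vapply(spots, function(sp)
    any(vapply(masks, lit_holds_r, TRUE, mask = sp[1L], pos = sp[2L])), TRUE)
  list(rule_ok = rule_ok, spot_ok = spot_ok)
}

#' Check a program against a linear Kripke model
#'
#' Verifies every causal rule and every observation spot of `p` on the
#' model: a normal rule requires, for every world where an effect literal
#' holds, a strictly earlier world where the whole cause set holds; a
#' persistent rule additionally requires the cause in the effect's world;
#' a remnant rule accepts the effect literal in the immediately preceding
#' world as an alternative to an earlier cause (an effect in the first
#' world requires the cause alongside it).  Observation spots must hold in
#' at least one world.
#'
#' @param model A [gubs_history()] (or the result of [extract_history()]).
#' @param p A macro-expanded [gubs_program()].
#' @param engine `"r"` or `"cpp"`; both implement the same semantics (the
#'   C++ kernel also drives the bounded enumeration functions).
#' @return Logical scalar with attribute `report`: a data frame with one
#'   row per rule and spot and its verdict.
#' @export
satisfies <- function(model, p, engine = c("r", "cpp")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "gubs_history"))
  atoms <- semantic_atoms(list(p), list(model))
  enc <- encode_program(p, atoms)
  masks <- world_masks(model, atoms)
  res <- if (engine == "r") check_model_r(masks, enc$rules, enc$spots)
         else cpp_check_model(as.integer(masks), enc$rules, enc$spots)
  items <- data.frame(
    item = c(vapply(p$rules, rule_token, ""),
             vapply(unname(p$spots), function(s) paste0("obs_", s$label), "")),
    type = c(vapply(p$rules, `[[`, "", "kind"),
             rep("spot", length(p$spots))),
    satisfied = c(as.logical(res$rule_ok), as.logical(res$spot_ok)),
    stringsAsFactors = FALSE)
  structure(all(items$satisfied), report = items, class = "gubs_verdict")
}

#' @export
print.gubs_verdict <- function(x, ...) {
  cat(if (isTRUE(c(x))) "satisfied\n" else "NOT satisfied\n")
  rep <- attr(x, "report")
  bad <- rep[!rep$satisfied, , drop = FALSE]
  if (nrow(bad)) {
    cat("failing items:\n")
    for (i in seq_len(nrow(bad)))
      cat("  ", bad$item[i], "\n", sep = "")
  }
  invisible(x)
}

default_bound <- function(p) length(p$rules) + 2L

#' Observability of a ground program
#'
#' A program is observable when some linear Kripke model with at most
#' `bound` worlds over the program's atom alphabet satisfies it -- i.e.
#' the described behaviour is not infeasible.  Implemented by bounded
#' depth-first enumeration with early exit on the first witness.
#'
#' @param p Ground, macro-expanded [gubs_program()].
#' @param bound Maximum number of worlds (default: number of rules + 2).
#' @param max_nodes Enumeration budget; exceeding it is an error, not a
#'   verdict.
#' @return Logical; when `TRUE`, attribute `witness` holds the satisfying
#'   worlds as character sets of atoms.
#' @export
observable <- function(p, bound = NULL, max_nodes = 2e7) {
  if (!is_ground(p))
    stop("observability requires a ground program", call. = FALSE)
  if (is.null(bound)) bound <- default_bound(p)
  stopifnot(bound >= 1L)
  atoms <- semantic_atoms(list(p))
  enc <- encode_program(p, atoms)
  res <- cpp_exists_model(length(atoms), as.integer(bound), enc$rules,
                          enc$spots, as.numeric(max_nodes))
  if (res$status == 2L)
    stop("observability search exceeded ", max_nodes, " nodes", call. = FALSE)
  found <- res$status == 1L
  structure(found,
            witness = if (found) decode_worlds(res$worlds, atoms) else NULL,
            nodes = res$nodes)
}

#' Bounded behavioural inclusion
#'
#' `q` behaviourally includes `p` when every linear Kripke model
#' satisfying `q` also satisfies `p`.  Checked exhaustively over all
#' models with at most `bound` worlds whose worlds range over the union
#' atom alphabet of both programs; this is bounded (not full) logical
#' consequence.
#'
#' @param q,p Ground, macro-expanded programs (covering and covered).
#' @param bound Maximum number of worlds (default: rules of `p` + 2).
#' @param max_nodes Enumeration budget; exceeding it is an error.
#' @return Logical; when `FALSE`, attribute `counterexample` holds a model
#'   satisfying `q` but not `p`.
#' @export
behaviourally_includes <- function(q, p, bound = NULL, max_nodes = 2e7) {
  if (!is_ground(q) || !is_ground(p))
    stop("behavioural inclusion requires ground programs", call. = FALSE)
  if (is.null(bound)) bound <- default_bound(p)
  stopifnot(bound >= 1L)
  atoms <- semantic_atoms(list(q, p))
  enc_q <- encode_program(q, atoms)
  enc_p <- encode_program(p, atoms)
  res <- cpp_includes(length(atoms), as.integer(bound), enc_q$rules,
                      enc_q$spots, enc_p$rules, enc_p$spots,
                      as.numeric(max_nodes))
  if (res$status == 2L)
    stop("inclusion check exceeded ", max_nodes, " nodes", call. = FALSE)
  ok <- res$status == 0L
  structure(ok,
            counterexample = if (!ok) decode_worlds(res$worlds, atoms)
                             else NULL,
            nodes = res$nodes)
}

#' Verify the subsumption relation between two causal-rule kinds
#'
#' Enumerates all linear models up to `bound` worlds over the alphabet of
#' a single cause atom and a single effect atom and confirms that every
#' model satisfying the stronger rule kind also satisfies the weaker one
#' (persistent implies normal implies remnant).
#'
#' @param strong,weak Rule kinds (`"normal"`, `"persistent"`, `"remnant"`).
#' @param bound Maximum world count (>= 1).
#' @return Logical; when `FALSE`, attribute `witness` is a separating
#'   model satisfying `strong` but not `weak`.
#' @export
subsumption_check <- function(strong, weak, bound = 6L) {
  strong <- match.arg(strong, RULE_KINDS)
  weak <- match.arg(weak, RULE_KINDS)
  stopifnot(bound >= 1L)
  mk <- function(kind)
    gubs_program(rules = list(causal_rule(kind,
                                          list(state_literal("C")),
                                          list(state_literal("E")))))
  res <- behaviourally_includes(mk(strong), mk(weak), bound = bound)
  structure(as.logical(res), witness = attr(res, "counterexample"))
}
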