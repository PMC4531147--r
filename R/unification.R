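# ACI-unification of a goal program against a tuple of library components.
#
# Program assembly is associative, commutative and idempotent, so
# unification works on rule sets: goal rule i is matched against the
# causal rules of the component occupying slot i of the candidate tuple,
# extending a substitution of goal variables by library constants.  The
# functional-synthesis calculus behind the derivations:
#   Inst.  an observable instance of (a part of) a library component is
#          synthesized under a substitution;
#   Com.   assembly is commutative (results are canonicalized);
#   Cont.  duplicated rules/components contract;
#   Asm.   two partial syntheses with compatible substitutions assemble,
#          provided the merged assembly stays observable.
#
# Substitution discipline: distinct goal variables map to distinct
# images, and never to a constant already occurring in the goal (a
# variable abstracts a part NOT named by the program).

#' Create a substitution
#'
#' @param map Named character vector: variable name -> agent name
#'   (constant or variable image).
#' @param forbidden Constant names that images may not take (the goal's
#'   own constants).
#' @return Object of class `gubs_subst`.
#' @export
substitution <- function(map = character(), forbidden = character()) {
  map <- unlist(map)
  if (length(map)) {
    stopifnot(!is.null(names(map)), all(nzchar(names(map))))
    bad <- names(map)[grepl("^[A-Z]", names(map))]
    if (length(bad))
      stop("substitution keys must be variables (lower-case): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(map))
      stop("substitution must be injective", call. = FALSE)
    clash <- intersect(map[grepl("^[A-Z]", map)], forbidden)
    if (length(clash))
      stop("variable may not map to a goal constant: ",
           paste(clash, collapse = ", "), call. = FALSE)
  }
  structure(list(map = map, forbidden = forbidden), class = "gubs_subst")
}

# extend s with var -> image; NULL when the extension is inadmissible
subst_extend <- function(s, var, image) {
  cur <- s$map[var]
  if (!is.na(cur)) {
    if (identical(unname(cur), image)) return(s) else return(NULL)
  }
  if (grepl("^[A-Z]", image) && image %in% s$forbidden) return(NULL)
  if (image %in% s$map) return(NULL)  # injectivity
  s$map[var] <- image
  s
}

subst_key <- function(s) {
  if (!length(s$map)) return("")
  o <- order(names(s$map), method = "radix")
  paste(names(s$map)[o], s$map[o], sep = "\036", collapse = "\035")
}

#' @export
print.gubs_subst <- function(x, ...) {
  if (!length(x$map)) cat("{ }\n")
  else cat("{", paste(names(x$map), "->", x$map, collapse = ", "), "}\n")
  invisible(x)
}

#' Apply a substitution to a program or rule
#'
#' @param x A [gubs_program()] or [causal_rule()].
#' @param s A [substitution()].
#' @export
apply_substitution <- function(x, s) {
  stopifnot(inherits(s, "gubs_subst"))
  map <- as.list(s$map)
  if (inherits(x, "gubs_rule")) substitute_rule(x, map)
  else substitute_program(x, map)
}

# can literal lp (goal) be matched to lq (component) under s?
# returns the (possibly extended) substitution, or NULL
lit_unify <- function(lp, lq, s, goal_decls, comp_decls) {
  if (lp$polarity != lq$polarity) return(NULL)
  qp <- lp$qualifier; qq <- lq$qualifier
  if (qp$type != qq$type || !identical(qp$value, qq$value)) return(NULL)
  a <- lp$agent
  if (is_constant_agent(a)) {
    if (a$name == lq$agent$name) s else NULL
  } else {
    img <- s$map[a$name]
    if (!is.na(img))
      return(if (identical(unname(img), lq$agent$name)) s else NULL)
    # binding a fresh variable: respect declared attribute capacity
    if (declared_attr_count(a$name, goal_decls) >
        declared_attr_count(lq$agent$name, comp_decls)) return(NULL)
    if (qp$type == "label" && grepl("^[A-Z]", lq$agent$name)) {
      d <- comp_decls[[lq$agent$name]]
      if (is.null(d) || !(qp$value %in% decl_labels(d))) return(NULL)
    }
    subst_extend(s, a$name, lq$agent$name)
  }
}

# injective assignment of all p-literals to q-literals on one side,
# threading the substitution; returns list of substitutions
side_unify <- function(p_lits, q_lits, s, goal_decls, comp_decls) {
  results <- list()
  nq <- length(q_lits)
  rec <- function(i, s, used) {
    effort_bump("unify_nodes")
    if (i > length(p_lits)) {
      results[[length(results) + 1L]] <<- s
      return(invisible(NULL))
    }
    for (j in seq_len(nq)) {
      if (used[j]) next
      s2 <- lit_unify(p_lits[[i]], q_lits[[j]], s, goal_decls, comp_decls)
      if (!is.null(s2)) rec(i + 1L, s2, `[<-`(used, j, TRUE))
    }
  }
  rec(1L, s, rep(FALSE, nq))
  results
}

#' Unify a goal rule with a component rule
#'
#' Computes all extensions of `s` under which the cause set of `p` maps
#' injectively into the cause set of `q` and likewise for effects,
#' preserving polarity, rule kind, qualifiers, compartment scope and
#' declared attribute capacity.  Context agents participate as cause
#' conjuncts.
#'
#' @param p Goal rule; `q` component rule (both macro-expanded).
#' @param s A [substitution()] to extend.
#' @param goal_decls,comp_decls Declaration lists for attribute checks.
#' @return List of [substitution()]s (empty on failure).
#' @export
unify_rule <- function(p, q, s = substitution(), goal_decls = list(),
                       comp_decls = list()) {
  if (p$kind != q$kind) return(list())
  pe <- effective_rule1(p)
  qe <- effective_rule1(q)
  if (pe$path != qe$path) return(list())
  out <- list()
  for (s1 in side_unify(pe$cause, qe$cause, s, goal_decls, comp_decls))
    for (s2 in side_unify(pe$effect, qe$effect, s1, goal_decls, comp_decls))
      out[[length(out) + 1L]] <- s2
  # distinct extensions only
  out[!duplicated(vapply(out, subst_key, ""))]
}

# union of the distinct components of a tuple as one assembly program
assemble_program <- function(comp_programs) {
  decls <- list(); rules <- list(); spots <- list()
  seen_rule <- character(); seen_decl <- character(); seen_spot <- character()
  for (cp in comp_programs) {
    for (d in unname(cp$declarations)) {
      if (d$agent$name %in% seen_decl) next
      seen_decl <- c(seen_decl, d$agent$name)
      decls <- c(decls, list(d))
    }
    for (r in cp$rules) {
      tk <- rule_token(r)
      if (tk %in% seen_rule) next  # Cont.: duplicate rules contract
      seen_rule <- c(seen_rule, tk)
      rules <- c(rules, list(r))
    }
    for (sp in unname(cp$spots)) {
      k <- paste(sp$label, lit_token(sp$observed))
      if (k %in% seen_spot) next
      seen_spot <- c(seen_spot, k)
      spots <- c(spots, list(sp))
    }
  }
  gubs_program(decls, rules, spots)
}

new_synthesis <- function(tuple, covered, s, assembly, derivation) {
  structure(list(components = tuple,
                 component_set = sort(unique(tuple), method = "radix"),
                 covered = covered,
                 substitution = s,
                 derivation = derivation,
                 assembly = assembly),
            class = "gubs_synthesis")
}

synthesis_key <- function(r)
  paste(paste(sort(r$components, method = "radix"), collapse = ","),
        subst_key(r$substitution), sep = "|")

#' @export
print.gubs_synthesis <- function(x, ...) {
  cat("components:", paste(x$components, collapse = ", "), "\n")
  cat("sigma: ")
  print(x$substitution)
  cat("derivation:", paste(x$derivation, collapse = " "), "\n")
  invisible(x)
}

derivation_of <- function(tuple) {
  u <- unique(tuple)
  c(paste0("Inst(", u, ")"),
    rep("Cont.", length(tuple) - length(u)),
    rep("Asm.", max(0L, length(u) - 1L)))
}

# goal spots must be covered by assembly spots under sigma
spots_covered <- function(goal, assembly, s) {
  if (!length(goal$spots)) return(TRUE)
  have <- vapply(unname(assembly$spots),
                 function(sp) lit_token(sp$observed), "")
  all(vapply(unname(goal$spots), function(sp)
    lit_token(substitute_literal(sp$observed, as.list(s$map))) %in% have,
    TRUE))
}

#' ACI-unification of a goal against a component tuple
#'
#' Backtracks over, for each goal rule, the causal rules of the component
#' in the corresponding tuple slot and all admissible substitution
#' extensions.  Complete substitutions yield synthesis results:
#' the assembly of the tuple's distinct components (duplicates contracted)
#' under the substitution, kept only when observable and when every goal
#' observation spot is covered.  Results are canonicalized modulo
#' commutativity of assembly and deduplicated.
#'
#' @param goal Macro-expanded [gubs_program()].
#' @param tuple Character vector of component names, one per goal rule.
#' @param lib A [gubs_library()].
#' @param observability_bound World bound for the observability check of
#'   each result (default 3; short witnesses suffice for typical
#'   repression-style libraries, raise for unusual shapes).
#' @return List of `gubs_synthesis` results; empty when unification fails.
#' @export
aci_unify <- function(goal, tuple, lib, observability_bound = 3L) {
  n <- length(goal$rules)
  stopifnot(length(tuple) == n)
  comps <- lapply(tuple, function(nm) {
    cp <- lib$components[[nm]]
    if (is.null(cp)) stop("unknown component: ", nm, call. = FALSE)
    cp
  })
  s0 <- substitution(forbidden = constants_of(goal))
  sigmas <- list()
  rec <- function(i, s) {
    if (i > n) {
      sigmas[[length(sigmas) + 1L]] <<- s
      return(invisible(NULL))
    }
    cp <- comps[[i]]
    for (q in cp$rules)
      for (s2 in unify_rule(goal$rules[[i]], q, s, goal$declarations,
                            cp$declarations))
        rec(i + 1L, s2)
  }
  rec(1L, s0)
  sigmas <- sigmas[!duplicated(vapply(sigmas, subst_key, ""))]
  out <- list()
  for (s in sigmas) {
    assembly <- apply_substitution(assemble_program(
      lapply(unique(tuple), function(nm) lib$components[[nm]])), s)
    if (!spots_covered(goal, assembly, s)) next
    obs <- tryCatch(observable(assembly, bound = observability_bound),
                    error = function(e) stop(
                      "observability check failed for assembly {",
                      paste(unique(tuple), collapse = ", "), "}: ",
                      conditionMessage(e), call. = FALSE))
    if (!isTRUE(as.logical(obs))) next
    out[[length(out) + 1L]] <-
      new_synthesis(tuple, seq_len(n), s, assembly, derivation_of(tuple))
  }
  out[!duplicated(vapply(out, synthesis_key, ""))]
}

#' Instantiate a library component under a substitution
#'
#' The Inst. step of the synthesis calculus: the substituted component
#' program, accepted only if observable.  Any textually included part of
#' the component may be the matched part, but the physical part comes
#' whole, so the full component enters the result.
#'
#' @param component A component [gubs_program()].
#' @param s A [substitution()].
#' @param observability_bound World bound for the observability check.
#' @return The substituted program.
#' @export
apply_inst <- function(component, s = substitution(),
                       observability_bound = 3L) {
  inst <- apply_substitution(component, s)
  if (!isTRUE(as.logical(observable(inst, bound = observability_bound))))
    stop("instance is not observable", call. = FALSE)
  inst
}

#' Assemble two partial synthesis results
#'
#' The Asm. step: substitutions must agree on shared variables; component
#' multisets are concatenated, the assembly is contracted (Cont.) and
#' observability is rechecked.  Commutative after canonicalization (Com.).
#'
#' @param r1,r2 `gubs_synthesis` results over the same goal and library.
#' @param lib The [gubs_library()] both results draw from.
#' @param observability_bound World bound for the observability recheck.
#' @return A merged `gubs_synthesis`.
#' @export
assemble <- function(r1, r2, lib, observability_bound = 3L) {
  shared <- intersect(names(r1$substitution$map), names(r2$substitution$map))
  for (v in shared)
    if (!identical(unname(r1$substitution$map[v]),
                   unname(r2$substitution$map[v])))
      stop("substitution conflict on variable ", v, ": ",
           r1$substitution$map[v], " vs ", r2$substitution$map[v],
           call. = FALSE)
  map <- c(r1$substitution$map,
           r2$substitution$map[setdiff(names(r2$substitution$map), shared)])
  s <- substitution(map, union(r1$substitution$forbidden,
                               r2$substitution$forbidden))
  tuple <- c(r1$components, r2$components)
  covered <- sort(unique(c(r1$covered, r2$covered)))
  assembly <- apply_substitution(assemble_program(
    lapply(unique(tuple), function(nm) lib$components[[nm]])), s)
  if (!isTRUE(as.logical(observable(assembly,
                                    bound = observability_bound))))
    stop("merged assembly is not observable", call. = FALSE)
  new_synthesis(tuple, covered, s, assembly,
                c(r1$derivation, r2$derivation, "Asm."))
}

# ---- brute-force oracle (testing only) --------------------------------------

# does ground goal rule p match component rule q textually (up to ACI)?
ground_rule_covered <- function(p, q) {
  if (p$kind != q$kind) return(FALSE)
  pe <- effective_rule1(p); qe <- effective_rule1(q)
  if (pe$path != qe$path) return(FALSE)
  ptk <- function(lits) vapply(lits, lit_token, "")
  all(ptk(pe$cause) %in% ptk(qe$cause)) &&
    all(ptk(pe$effect) %in% ptk(qe$effect))
}

#' Brute-force synthesis oracle
#'
#' Independent reference for testing: enumerates every full substitution
#' of the goal's variables by library constants (injective, avoiding the
#' goal's own constants) and, for each, every assignment of goal rules to
#' components whose rules textually cover them; keeps observable
#' assemblies.  Exhaustive, with resource guards; not part of the
#' compilation pipeline.
#'
#' @param goal Macro-expanded [gubs_program()].
#' @param lib A small [gubs_library()] (at most 8 components).
#' @param max_sigma Guard on the number of substitutions enumerated.
#' @param observability_bound World bound for the observability check.
#' @return List of solutions, each `list(tuple, components, sigma)`;
#'   canonical and deduplicated.
#' @export
brute_force_oracle <- function(goal, lib, max_sigma = 20000,
                               observability_bound = 3L) {
  stopifnot(inherits(lib, "gubs_library"))
  if (length(lib$components) > 8L)
    stop("oracle guard: library too large", call. = FALSE)
  vars <- variables_of(goal)
  if (length(vars) > 4L)
    stop("oracle guard: too many variables", call. = FALSE)
  if (!length(goal$rules)) {
    return(list(list(tuple = character(), components = character(),
                     sigma = character())))
  }
  lib_constants <- sort(unique(unlist(lapply(lib$components, constants_of))),
                        method = "radix")
  candidates <- setdiff(lib_constants, constants_of(goal))
  # all injective assignments vars -> candidates
  sigmas <- list(character())
  for (v in vars) {
    nxt <- list()
    for (partial in sigmas)
      for (cand in setdiff(candidates, partial)) {
        p2 <- c(partial, stats::setNames(cand, v))
        nxt[[length(nxt) + 1L]] <- p2
      }
    sigmas <- nxt
    if (length(sigmas) > max_sigma)
      stop("oracle guard: substitution space too large", call. = FALSE)
  }
  obs_cache <- new.env(parent = emptyenv())
  solutions <- list()
  for (map in sigmas) {
    ground_goal <- substitute_program(goal, as.list(map))
    slot_sets <- lapply(ground_goal$rules, function(p) {
      hits <- character()
      for (cn in names(lib$components))
        if (any(vapply(lib$components[[cn]]$rules, ground_rule_covered,
                       TRUE, p = p)))
          hits <- c(hits, cn)
      hits
    })
    if (any(!vapply(slot_sets, length, 0L))) next
    # spots of the goal must be present in the assembly
    grid <- expand.grid(slot_sets, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      tuple <- unname(unlist(grid[i, ], use.names = FALSE))
      set <- sort(unique(tuple), method = "radix")
      key <- paste(set, collapse = ",")
      obs <- obs_cache[[key]]
      assembly <- assemble_program(lapply(set, function(nm)
        lib$components[[nm]]))
      if (is.null(obs)) {
        obs <- isTRUE(as.logical(observable(assembly,
                                            bound = observability_bound)))
        obs_cache[[key]] <- obs
      }
      if (!obs) next
      if (length(ground_goal$spots)) {
        have <- vapply(unname(assembly$spots),
                       function(sp) lit_token(sp$observed), "")
        want <- vapply(unname(ground_goal$spots),
                       function(sp) lit_token(sp$observed), "")
        if (!all(want %in% have)) next
      }
      solutions[[length(solutions) + 1L]] <- list(tuple = tuple,
                                                  components = set,
                                                  sigma = map)
    }
  }
  keys <- vapply(solutions, function(sol)
    paste(paste(sort(sol$tuple, method = "radix"), collapse = ","),
          paste(names(sol$sigma), sol$sigma, sep = ">", collapse = ";"),
          sep = "|"), "")
  solutions[!duplicated(keys)]
}
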