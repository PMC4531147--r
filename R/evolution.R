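# Two-stage compilation: exhaustive candidate enumeration for small
# libraries, and a directed evolutionary search for large ones.
#
# An individual is a tuple of components, one gene (slot) per goal rule,
# drawn from that rule's association set -- the "directed" part: genes can
# only take values that do not obviously doom the unification.  Fitness is
# lexicographic: feasibility, then number of unified goal rules
# (maximized), then number of distinct components used (minimized).

#' Compiler search configuration
#'
#' @param seed Integer seed; mandatory (the GA path and population
#'   initialization are seeded, and runs are fully reproducible).
#' @param population Population size.
#' @param generations Maximum generations.
#' @param tournament Tournament size for selection.
#' @param crossover One-point crossover probability.
#' @param mutation Per-gene mutation probability (resampling from the
#'   gene's association set).
#' @param stagnation Stop after this many generations without improvement
#'   of the best fitness.
#' @param exhaustive_threshold Library sizes up to this use exhaustive
#'   candidate enumeration instead of the GA.
#' @param max_candidates Guard on the exhaustive enumeration size; larger
#'   products fall through to the GA.
#' @param observability_bound World bound for observability checks of
#'   assemblies.
#' @param max_eval_nodes Backtracking budget per fitness evaluation.
#' @param sigma_probe Budget of candidate substitutions enumerated when
#'   seeding the GA population substitution-first.
#' @param stop_on_success Stop the GA at the end of the first generation
#'   that produced a full covering.
#' @return Object of class `gubs_config`.
#' @export
gubs_config <- function(seed, population = 50L, generations = 200L,
                        tournament = 3L, crossover = 0.8, mutation = 0.1,
                        stagnation = 20L, exhaustive_threshold = 12L,
                        max_candidates = 20000L, observability_bound = 3L,
                        max_eval_nodes = 5000L, sigma_probe = 20000L,
                        stop_on_success = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(seed = as.integer(seed), population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 crossover = crossover, mutation = mutation,
                 stagnation = as.integer(stagnation),
                 exhaustive_threshold = as.integer(exhaustive_threshold),
                 max_candidates = as.integer(max_candidates),
                 observability_bound = as.integer(observability_bound),
                 max_eval_nodes = as.integer(max_eval_nodes),
                 sigma_probe = as.integer(sigma_probe),
                 stop_on_success = isTRUE(stop_on_success)),
            class = "gubs_config")
}

# lexicographic fitness comparison: is f1 strictly better than f2?
fitness_better <- function(f1, f2) {
  if (f1$feasible != f2$feasible) return(f1$feasible)
  if (f1$n_unified != f2$n_unified) return(f1$n_unified > f2$n_unified)
  f1$n_components < f2$n_components
}

fitness_key <- function(f)
  sprintf("%d|%05d|%05d", as.integer(f$feasible), f$n_unified,
          -f$n_components + 99999L)

#' Evaluate an individual
#'
#' Runs unification restricted to the individual's components:
#' `n_unified` is the size of the largest subset of goal rules unifiable
#' with a consistent substitution (found by capped backtracking over
#' include/skip choices per rule), `n_components` counts the distinct
#' components of the covered slots, and `feasible` records a full cover.
#'
#' @param genes Character vector of component names, one per goal rule.
#' @param goal Macro-expanded [gubs_program()].
#' @param lib A [gubs_library()].
#' @param cfg A [gubs_config()] (for the evaluation budget).
#' @return `list(feasible, n_unified, n_components)`.
#' @export
evaluate_individual <- function(genes, goal, lib, cfg) {
  n <- length(goal$rules)
  stopifnot(length(genes) == n)
  effort_bump("evaluations")
  if (!n) return(list(feasible = TRUE, n_unified = 0L, n_components = 0L))
  comps <- lapply(genes, function(nm) lib$components[[nm]])
  s0 <- substitution(forbidden = constants_of(goal))
  # full-cover probe first: plain backtracking without skip branches
  nodes <- 0L
  full <- FALSE
  probe <- function(i, s) {
    if (full || nodes > cfg$max_eval_nodes) return(invisible(NULL))
    nodes <<- nodes + 1L
    effort_bump("unify_nodes")
    if (i > n) { full <<- TRUE; return(invisible(NULL)) }
    for (q in comps[[i]]$rules)
      for (s2 in unify_rule(goal$rules[[i]], q, s, goal$declarations,
                            comps[[i]]$declarations))
        probe(i + 1L, s2)
  }
  probe(1L, s0)
  if (full)
    return(list(feasible = TRUE, n_unified = n,
                n_components = length(unique(genes)),
                uncovered = integer()))
  # capped search over include/skip choices for partial credit
  best <- list(count = 0L, used = integer())
  nodes <- 0L
  rec <- function(i, s, covered) {
    if (nodes > cfg$max_eval_nodes) return(invisible(NULL))
    nodes <<- nodes + 1L
    effort_bump("unify_nodes")
    if (length(covered) + (n - i + 1L) <= best$count)
      return(invisible(NULL))  # cannot beat the incumbent
    if (i > n) {
      if (length(covered) > best$count)
        best <<- list(count = length(covered), used = covered)
      return(invisible(NULL))
    }
    for (q in comps[[i]]$rules)
      for (s2 in unify_rule(goal$rules[[i]], q, s, goal$declarations,
                            comps[[i]]$declarations))
        rec(i + 1L, s2, c(covered, i))
    rec(i + 1L, s, covered)  # skip rule i
  }
  rec(1L, s0, integer())
  list(feasible = best$count == n,
       n_unified = best$count,
       n_components = length(unique(genes[best$used])),
       uncovered = setdiff(seq_len(n), best$used))
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

# substitution-first seeding: enumerate candidate substitutions (capped,
# in seeded random order), ground the goal, and assemble individuals from
# components whose rules textually cover each slot.  Complements the GA's
# gene-level search with joint-consistency information; the enumeration
# is exponential in the number of variables only.
sigma_seeded_individuals <- function(goal, lib, map, cfg, want) {
  vars <- variables_of(goal)
  if (!length(vars) || want <= 0L) return(list())
  consts <- sort(unique(unlist(lapply(lib$components, constants_of))),
                 method = "radix")
  candidates <- setdiff(consts, constants_of(goal))
  if (length(candidates) < length(vars)) return(list())
  slot_order <- order(vapply(map$components, length, 0L))
  out <- list()
  tried <- 0L
  rec <- function(i, sigma) {
    if (length(out) >= want || tried >= cfg$sigma_probe)
      return(invisible(NULL))
    if (i > length(vars)) {
      tried <<- tried + 1L
      effort_bump("unify_nodes")
      ground <- substitute_program(goal, as.list(sigma))
      slot_sets <- vector("list", length(map$pairs))
      for (j in slot_order) {
        df <- map$pairs[[j]]
        hits <- unique(df$component[vapply(seq_len(nrow(df)), function(k)
          ground_rule_covered(ground$rules[[j]],
                              lib$components[[df$component[k]]]$rules[[df$rule[k]]]),
          TRUE)])
        if (!length(hits)) return(invisible(NULL))
        slot_sets[[j]] <- hits
      }
      genes <- vapply(slot_sets, sample1, "")
      out[[length(out) + 1L]] <<- list(genes = genes)
      return(invisible(NULL))
    }
    for (cand in sample(setdiff(candidates, sigma))) {
      if (length(out) >= want || tried >= cfg$sigma_probe) break
      rec(i + 1L, c(sigma, stats::setNames(cand, vars[i])))
    }
  }
  rec(1L, character())
  out
}

random_individual <- function(map, goal, lib, tries = 20L) {
  for (k in seq_len(tries)) {
    genes <- vapply(map$components, sample1, "")
    comps <- lapply(genes, function(nm) lib$components[[nm]])
    if (isTRUE(agent_constraints_ok(goal, comps)))
      return(list(genes = genes, feasible_genes = TRUE))
  }
  list(genes = vapply(map$components, sample1, ""), feasible_genes = FALSE)
}

#' One generation of the directed evolutionary search
#'
#' Tournament selection on fitness, one-point crossover over the gene
#' vector, per-gene mutation resampling from the rule's association set;
#' offspring violating the agent constraints are resampled (directedness);
#' elitism keeps the best individual.  Fully reproducible from the RNG
#' state.
#'
#' @param pop List of individuals `list(genes, fitness)`.
#' @param map An [associate()] result.
#' @param goal,lib,cfg As in [evaluate_individual()].
#' @return The next population, same size, fitness evaluated.
#' @export
evolve_step <- function(pop, map, goal, lib, cfg) {
  n <- length(pop)
  stopifnot(n >= 1L)
  keys <- vapply(pop, function(ind) fitness_key(ind$fitness), "")
  elite <- pop[[which.max(rank(keys, ties.method = "first"))]]
  pick <- function() {
    idx <- sample.int(n, min(cfg$tournament, n), replace = FALSE)
    idx[which.max(rank(keys[idx], ties.method = "first"))]
  }
  genes_ok <- function(genes)
    isTRUE(agent_constraints_ok(goal, lapply(genes, function(nm)
      lib$components[[nm]])))
  offspring <- list(elite)
  while (length(offspring) < n) {
    i1 <- pick()
    g1 <- pop[[i1]]$genes
    g2 <- pop[[pick()]]$genes
    child <- g1
    L <- length(child)
    if (L >= 2L && stats::runif(1) < cfg$crossover) {
      cut <- sample.int(L - 1L, 1L)
      child <- c(g1[seq_len(cut)], g2[(cut + 1L):L])
    }
    # directedness: slots that failed unification in the parent mutate
    # preferentially
    uncov <- pop[[i1]]$fitness$uncovered
    for (j in seq_len(L)) {
      pmut <- if (j %in% uncov) max(cfg$mutation, 0.5) else cfg$mutation
      if (stats::runif(1) < pmut)
        child[j] <- sample1(map$components[[j]])
    }
    if (L && !genes_ok(child)) {
      # directed repair: resample a fresh constraint-respecting individual
      child <- random_individual(map, goal, lib)$genes
    }
    fit <- evaluate_individual(child, goal, lib, cfg)
    offspring[[length(offspring) + 1L]] <- list(genes = child, fitness = fit)
  }
  offspring
}

# greedy repair of an infeasible individual: try alternative components
# for the slots whose rules failed to unify, keeping any improvement
local_repair <- function(ind, map, goal, lib, cfg, max_rounds = 3L) {
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (j in ind$fitness$uncovered) {
      for (cand in map$components[[j]]) {
        if (identical(cand, ind$genes[j])) next
        g2 <- ind$genes
        g2[j] <- cand
        f2 <- evaluate_individual(g2, goal, lib, cfg)
        if (fitness_better(f2, ind$fitness)) {
          ind$genes <- g2
          ind$fitness <- f2
          improved <- TRUE
          break
        }
      }
      if (ind$fitness$feasible) return(ind)
    }
    if (!improved) break
  }
  ind
}

order_solutions <- function(solutions) {
  if (!length(solutions)) return(solutions)
  keys <- vapply(solutions, function(r)
    paste(sprintf("%05d", length(r$component_set)),
          paste(r$component_set, collapse = ","),
          subst_key(r$substitution), sep = "|"), "")
  solutions[order(keys, method = "radix")]
}

#' Compile a goal program against a component library
#'
#' The full pipeline: macro expansion, local causal association of each
#' goal rule, candidate-tuple enumeration filtered by the agent
#' constraints and ACI-unification (exhaustive for libraries up to
#' `cfg$exhaustive_threshold` components), or the directed evolutionary
#' search for larger libraries.  All distinct solutions found are
#' returned, ordered by fitness (fewest distinct components first) and
#' then lexicographically.
#'
#' @param goal A [gubs_program()] (macros allowed; expanded internally).
#' @param lib A [gubs_library()].
#' @param cfg A [gubs_config()]; the seed governs every random draw.
#' @return Object of class `gubs_compilation`: `solutions`, `stats`
#'   (stage, association sizes, candidate/survivor counts, eliminations,
#'   effort counters), `seed`.
#' @export
gubs_compile <- function(goal, lib, cfg = gubs_config(seed = 1L)) {
  stopifnot(inherits(lib, "gubs_library"), inherits(cfg, "gubs_config"))
  goal <- expand_macros(goal)
  # Cont.: duplicated goal rules contract before matching
  toks <- vapply(goal$rules, rule_token, "")
  goal <- gubs_program(unname(goal$declarations), goal$rules[!duplicated(toks)],
                       unname(goal$spots))
  vr <- setdiff(variables_of(goal),
                unlist(lapply(effective_rules(goal), function(er)
                  vapply(c(er$cause, er$effect),
                         function(l) l$agent$name, ""))))
  if (length(vr))
    stop("variable(s) occurring only in observation spots cannot be bound: ",
         paste(vr, collapse = ", "), call. = FALSE)
  reset_effort()
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  if (!length(goal$rules)) {
    empty <- new_synthesis(character(), integer(),
                           substitution(), gubs_program(), character())
    return(structure(list(solutions = list(empty),
                          stats = list(stage = "exhaustive",
                                       associations = integer(),
                                       n_candidates = 1L, n_survivors = 1L,
                                       eliminations = list(),
                                       effort = effort_counters()),
                          seed = cfg$seed),
                     class = "gubs_compilation"))
  }
  map <- associate(goal, lib)
  if (length(map$orphans))
    stop(structure(class = c("gubsc_no_solution", "error", "condition"),
                   list(message = paste0(
                     "no component associates with goal rule(s): ",
                     paste(vapply(map$orphans, function(i)
                       rule_token(goal$rules[[i]]), ""), collapse = "; ")),
                     call = NULL)))
  assoc_sizes <- vapply(map$components, length, 0L)
  product <- prod(assoc_sizes)
  use_exhaustive <- length(lib$components) <= cfg$exhaustive_threshold &&
    product <= cfg$max_candidates
  solutions <- list()
  stats <- list(associations = assoc_sizes, seed = cfg$seed)
  if (use_exhaustive) {
    cand <- candidate_subsets(goal, lib, map,
                              max_candidates = cfg$max_candidates)
    stats$stage <- "exhaustive"
    stats$n_candidates <- cand$n_before
    stats$n_survivors <- length(cand$tuples)
    stats$eliminations <- cand$eliminated
    for (tuple in cand$tuples)
      solutions <- c(solutions,
                     aci_unify(goal, tuple, lib,
                               observability_bound = cfg$observability_bound))
  } else {
    stats$stage <- "evolutionary"
    seeded <- sigma_seeded_individuals(goal, lib, map, cfg,
                                       want = cfg$population %/% 2L)
    pop <- c(seeded,
             lapply(seq_len(cfg$population - length(seeded)), function(i)
               random_individual(map, goal, lib)))
    pop <- lapply(pop, function(ind) {
      ind$fitness <- evaluate_individual(ind$genes, goal, lib, cfg)
      ind
    })
    seen <- new.env(parent = emptyenv())
    harvest <- function(pop) {
      for (ind in pop) {
        if (!ind$fitness$feasible) next
        k <- paste(ind$genes, collapse = ",")
        if (!is.null(seen[[k]])) next
        seen[[k]] <- TRUE
        solutions <<- c(solutions,
                        aci_unify(goal, ind$genes, lib,
                                  observability_bound =
                                    cfg$observability_bound))
      }
    }
    harvest(pop)
    best_key <- max(vapply(pop, function(i) fitness_key(i$fitness), ""))
    stagnant <- 0L
    gens <- 0L
    restarts <- 0L
    log <- character()
    while (gens < cfg$generations &&
           !(cfg$stop_on_success && length(solutions))) {
      if (stagnant >= cfg$stagnation) {
        # random restart around the elite: reseed everyone else
        keys <- vapply(pop, function(i) fitness_key(i$fitness), "")
        elite <- pop[[which.max(rank(keys, ties.method = "first"))]]
        fresh <- c(sigma_seeded_individuals(goal, lib, map, cfg,
                                            want = cfg$population %/% 2L),
                   lapply(seq_len(cfg$population), function(i)
                     random_individual(map, goal, lib)))
        pop <- c(list(elite), fresh[seq_len(cfg$population - 1L)])
        pop[-1] <- lapply(pop[-1], function(ind) {
          ind$fitness <- evaluate_individual(ind$genes, goal, lib, cfg)
          ind
        })
        harvest(pop)
        stagnant <- 0L
        restarts <- restarts + 1L
        next
      }
      pop <- evolve_step(pop, map, goal, lib, cfg)
      gens <- gens + 1L
      harvest(pop)
      # memetic step: repair the best individual's failing slots
      keys <- vapply(pop, function(i) fitness_key(i$fitness), "")
      bi <- which.max(rank(keys, ties.method = "first"))
      if (!pop[[bi]]$fitness$feasible) {
        rep_ind <- local_repair(pop[[bi]], map, goal, lib, cfg)
        if (fitness_better(rep_ind$fitness, pop[[bi]]$fitness)) {
          pop[[bi]] <- rep_ind
          harvest(list(rep_ind))
        }
      }
      bk <- max(vapply(pop, function(i) fitness_key(i$fitness), ""))
      if (bk > best_key) { best_key <- bk; stagnant <- 0L }
      else stagnant <- stagnant + 1L
      log <- c(log, sprintf("gen %d best %s", gens, bk))
    }
    stats$restarts <- restarts
    stats$generations <- gens
    stats$log <- log
    stats$n_candidates <- NA_integer_
    stats$n_survivors <- NA_integer_
    stats$eliminations <- list()
  }
  solutions <- solutions[!duplicated(vapply(solutions, synthesis_key, ""))]
  # GA results are re-verified by construction: they come out of aci_unify
  stats$effort <- effort_counters()
  structure(list(solutions = order_solutions(solutions), stats = stats,
                 seed = cfg$seed),
            class = "gubs_compilation")
}

#' @export
print.gubs_compilation <- function(x, ...) {
  cat(sprintf("compilation (%s stage, seed %d): %d solution(s)\n",
              x$stats$stage, x$seed, length(x$solutions)))
  for (r in x$solutions[seq_len(min(5L, length(x$solutions)))]) {
    cat("  {", paste(r$component_set, collapse = ", "), "}  sigma ")
    print(r$substitution)
  }
  invisible(x)
}
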