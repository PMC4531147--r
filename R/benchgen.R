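# Synthetic benchmark generator: random component libraries and goal
# programs solvable by construction.  A goal is built by sampling rules
# from planted components and then abstracting a chosen set of constants
# into variables (wholly, so a constant never both remains in the goal
# and serves as a variable's intended image -- preserving the freshness
# discipline of substitutions).
#
# Generated rules are repression-style (positive causes, negated
# effects), the shape of the worked examples; assemblies of such rules
# always admit a short observability witness.

#' Benchmark configuration
#'
#' @param n_components Library size.
#' @param rules_per_component Length-2 integer range of rules per
#'   component.
#' @param n_goal_rules Number of causal rules in the goal.
#' @param n_variables Number of variable agents in the goal (constants
#'   abstracted away).
#' @param n_constants Number of distinct constants remaining in the goal.
#' @param cause_size Length-2 range of cause-set sizes.
#' @param seed Integer seed; generation is fully deterministic in it.
#' @return Object of class `gubs_benchcfg`.
#' @export
bench_config <- function(n_components = 100L, rules_per_component = c(1L, 2L),
                         n_goal_rules = 10L, n_variables = 3L,
                         n_constants = 5L, cause_size = c(1L, 2L), seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- list(n_components = as.integer(n_components),
              rules_per_component = as.integer(rules_per_component),
              n_goal_rules = as.integer(n_goal_rules),
              n_variables = as.integer(n_variables),
              n_constants = as.integer(n_constants),
              cause_size = as.integer(cause_size),
              seed = as.integer(seed))
  with(cfg, stopifnot(n_components >= 0L, n_goal_rules >= 0L,
                      n_variables >= 0L, n_constants >= 0L,
                      length(rules_per_component) == 2L,
                      rules_per_component[1] >= 1L,
                      rules_per_component[1] <= rules_per_component[2],
                      length(cause_size) == 2L, cause_size[1] >= 1L))
  if (cfg$n_goal_rules > 0L &&
      cfg$n_variables + cfg$n_constants > 2L * cfg$n_goal_rules)
    stop("infeasible configuration: a goal of ", cfg$n_goal_rules,
         " rules cannot exhibit ", cfg$n_variables + cfg$n_constants,
         " distinct agents", call. = FALSE)
  if (cfg$n_goal_rules > 0L && cfg$n_variables + cfg$n_constants < 1L)
    stop("infeasible configuration: goal rules need at least one agent",
         call. = FALSE)
  structure(cfg, class = "gubs_benchcfg")
}

# sample uniformly from an integer range given as c(lo, hi)
sample_range <- function(r) if (r[1] == r[2]) r[1] else
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

# one random repression-style rule over the given agent-name pool
random_rule <- function(pool, cause_size) {
  kind <- sample(RULE_KINDS, 1L)
  nc <- min(sample_range(cause_size), length(pool))
  cause_agents <- sample(pool, nc)
  effect_agent <- sample(pool, 1L)
  causal_rule(kind,
              lapply(cause_agents, function(a) state_literal(a)),
              list(state_literal(effect_agent, "absent")))
}

#' Generate a benchmark instance
#'
#' Builds a goal of `n_goal_rules` distinct rules over
#' `n_constants + n_variables` distinct agents, plants the rules verbatim
#' into library components (grouped by `rules_per_component`), pads the
#' library with random components to `n_components`, and finally
#' abstracts `n_variables` of the goal's constants into variables.  The
#' planted components and the inverse abstraction form a solution, so
#' every generated instance compiles.
#'
#' @param cfg A [bench_config()].
#' @return `list(library, goal, planted)` of class `gubs_bench`;
#'   `planted` holds the constructed solution tuple and substitution.
#' @export
bench_generate <- function(cfg) {
  stopifnot(inherits(cfg, "gubs_benchcfg"))
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  n_goal_agents <- cfg$n_constants + cfg$n_variables
  pool_size <- min(20L, max(n_goal_agents + 4L, 8L))
  pool <- sprintf("P%02d", seq_len(pool_size))
  goal_agents <- pool[seq_len(n_goal_agents)]
  abstracted <- if (cfg$n_variables)
    goal_agents[cfg$n_constants + seq_len(cfg$n_variables)] else character()

  goal_rules <- list()
  if (cfg$n_goal_rules > 0L) {
    # seed every goal agent into some rule, then fill randomly
    seen <- character()
    tries <- 0L
    required <- sample(goal_agents)
    while (length(goal_rules) < cfg$n_goal_rules) {
      tries <- tries + 1L
      if (tries > 200L * cfg$n_goal_rules)
        stop("could not generate ", cfg$n_goal_rules, " distinct rules over ",
             n_goal_agents, " agents", call. = FALSE)
      r <- random_rule(goal_agents, cfg$cause_size)
      missing <- setdiff(required, seen)
      if (length(missing)) {
        # force the next missing agents into this rule
        take <- missing[seq_len(min(2L, length(missing)))]
        eff_agent <- if (length(take) > 1L) take[2]
                     else sample(goal_agents, 1L)
        r <- causal_rule(sample(RULE_KINDS, 1L),
                         list(state_literal(take[1])),
                         list(state_literal(eff_agent, "absent")))
      }
      tk <- rule_token(r)
      if (tk %in% vapply(goal_rules, rule_token, "")) next
      goal_rules <- c(goal_rules, list(r))
      seen <- unique(c(seen, vapply(c(r$cause, r$effect),
                                    function(l) l$agent$name, "")))
    }
    left <- setdiff(required, seen)
    if (length(left))
      stop("could not place agent(s) ", paste(left, collapse = ", "),
           " in the goal", call. = FALSE)
  }

  # plant the goal rules verbatim into components
  planted_programs <- list()
  idx <- seq_along(goal_rules)
  slot_component <- integer(length(goal_rules))
  while (length(idx)) {
    take <- min(sample_range(cfg$rules_per_component), length(idx))
    planted_programs[[length(planted_programs) + 1L]] <-
      gubs_program(rules = goal_rules[idx[seq_len(take)]])
    slot_component[idx[seq_len(take)]] <- length(planted_programs)
    idx <- idx[-seq_len(take)]
  }
  n_planted <- length(planted_programs)
  if (n_planted > cfg$n_components)
    stop("infeasible configuration: ", cfg$n_goal_rules, " goal rules need ",
         n_planted, " components but the library holds only ",
         cfg$n_components, call. = FALSE)

  fillers <- lapply(seq_len(cfg$n_components - n_planted), function(i) {
    k <- sample_range(cfg$rules_per_component)
    gubs_program(rules = lapply(seq_len(k), function(j)
      random_rule(pool, cfg$cause_size)))
  })
  programs <- c(planted_programs, fillers)
  perm <- sample.int(length(programs))
  names_by_pos <- sprintf("B%03d", seq_along(programs))
  components <- stats::setNames(programs[perm], names_by_pos)
  planted_names <- names_by_pos[match(seq_len(n_planted), perm)]
  lib <- gubs_library(components,
                      source = sprintf("benchgen:seed=%d", cfg$seed))

  # abstract the chosen constants into variables (wholly)
  var_names <- sprintf("x%d", seq_len(cfg$n_variables))
  abs_map <- stats::setNames(var_names, abstracted)
  abstract_agent <- function(a) {
    if (!is.null(abs_map[a$name]) && !is.na(abs_map[a$name]))
      agent_ref(unname(abs_map[a$name])) else a
  }
  goal <- gubs_program(rules = lapply(goal_rules, function(r)
    causal_rule(r$kind,
                lapply(r$cause, function(l) {
                  l$agent <- abstract_agent(l$agent); l
                }),
                lapply(r$effect, function(l) {
                  l$agent <- abstract_agent(l$agent); l
                }),
                r$scope)))

  planted <- list(tuple = planted_names[slot_component],
                  sigma = stats::setNames(abstracted, var_names))
  structure(list(library = lib, goal = goal, planted = planted, cfg = cfg),
            class = "gubs_bench")
}

#' Scaling harness over a parameter grid
#'
#' Generates and compiles one instance per (variables, constants, seed)
#' cell and records success and the hardware-independent effort counters.
#' Wall-clock time is reported for information only; comparisons should
#' use the counters.
#'
#' @param n_variables,n_constants Integer vectors to cross.
#' @param seeds Integer vector of seeds (one instance per seed and cell).
#' @param base Named list of [bench_config()] overrides (e.g.
#'   `n_components`).
#' @param cfg_fn Function `seed -> gubs_config` for the compiler
#'   configuration.
#' @param csv Optional path; when given, the table is also written as CSV.
#' @return Data frame with one row per run: `n_variables`, `n_constants`,
#'   `seed`, `success`, `n_solutions`, `stage`, `effort`, `elapsed`.
#' @export
scaling_harness <- function(n_variables = 1:4, n_constants = 4L,
                            seeds = 1:5, base = list(),
                            cfg_fn = function(seed) gubs_config(seed = seed),
                            csv = NULL) {
  grid <- expand.grid(n_variables = n_variables, n_constants = n_constants,
                      seed = seeds, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    args <- utils::modifyList(
      list(n_variables = g$n_variables, n_constants = g$n_constants,
           seed = g$seed), base)
    bcfg <- do.call(bench_config, args)
    inst <- bench_generate(bcfg)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(gubs_compile(inst$goal, inst$library, cfg_fn(g$seed)),
                    error = function(e) NULL)
    elapsed <- proc.time()[["elapsed"]] - t0
    data.frame(n_variables = g$n_variables, n_constants = g$n_constants,
               seed = g$seed,
               success = !is.null(res) && length(res$solutions) > 0L,
               n_solutions = if (is.null(res)) 0L else length(res$solutions),
               stage = if (is.null(res)) NA_character_ else res$stats$stage,
               effort = if (is.null(res)) NA_real_
                        else unname(res$stats$effort["total"]),
               elapsed = elapsed)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
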