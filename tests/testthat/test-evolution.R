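# Fitness evaluation, the directed GA, and the two-stage compile driver.

fx <- gubs_fixtures()
goal <- fx$repressilator_goal
lib <- fx$repressilator_lib5
cfg <- gubs_config(seed = 1L)

test_that("evaluate_individual scores the worked tuples correctly", {
  f_ok <- evaluate_individual(c("Q2", "Q1", "Q3"), goal, lib, cfg)
  expect_true(f_ok$feasible)
  expect_identical(f_ok$n_unified, 3L)
  expect_identical(f_ok$n_components, 3L)
  f_bad <- evaluate_individual(c("Q2", "Q1", "Q4"), goal, lib, cfg)
  expect_false(f_bad$feasible)
  expect_identical(f_bad$n_unified, 2L)  # best partial cover
  f_empty <- evaluate_individual(character(), gubs_program(), lib, cfg)
  expect_true(f_empty$feasible)
  expect_identical(f_empty$n_unified, 0L)
  expect_identical(f_empty$n_components, 0L)
})

test_that("fitness comparison is lexicographic", {
  f <- function(feas, nu, nc)
    list(feasible = feas, n_unified = nu, n_components = nc)
  expect_true(gubsc:::fitness_better(f(TRUE, 3, 5), f(FALSE, 3, 1)))
  expect_true(gubsc:::fitness_better(f(FALSE, 3, 2), f(FALSE, 2, 1)))
  expect_true(gubsc:::fitness_better(f(TRUE, 3, 2), f(TRUE, 3, 3)))
  expect_false(gubsc:::fitness_better(f(TRUE, 3, 3), f(TRUE, 3, 3)))
})

test_that("elitism keeps an optimal population stable", {
  map <- associate(goal, lib)
  ind <- list(genes = c("Q2", "Q1", "Q3"))
  ind$fitness <- evaluate_individual(ind$genes, goal, lib, cfg)
  pop <- rep(list(ind), 6L)
  set.seed(7)
  for (i in 1:5) {
    pop <- evolve_step(pop, map, goal, lib, cfg)
    keys <- vapply(pop, function(x) gubsc:::fitness_key(x$fitness), "")
    best <- pop[[which.max(rank(keys, ties.method = "first"))]]
    expect_true(best$fitness$feasible)
    expect_identical(best$fitness$n_unified, 3L)
  }
})

test_that("evolution is reproducible and best fitness never degrades", {
  inst <- bench_generate(bench_config(
    n_components = 20, n_goal_rules = 5, n_variables = 2, n_constants = 3,
    seed = 11))
  map <- associate(inst$goal, inst$library)
  run <- function() {
    set.seed(123)
    pop <- lapply(1:12, function(i)
      gubsc:::random_individual(map, inst$goal, inst$library))
    pop <- lapply(pop, function(ind) {
      ind$fitness <- evaluate_individual(ind$genes, inst$goal, inst$library,
                                         cfg)
      ind
    })
    trail <- character()
    for (g in 1:8) {
      pop <- evolve_step(pop, map, inst$goal, inst$library, cfg)
      trail <- c(trail, max(vapply(pop, function(x)
        gubsc:::fitness_key(x$fitness), "")))
    }
    trail
  }
  t1 <- run()
  t2 <- run()
  expect_identical(t1, t2)              # same seed, same trajectory
  # elitism: the best fitness key never lexicographically decreases
  expect_true(all(t1[-1] >= t1[-length(t1)]))
})

test_that("compile dispatches by library size and records the stage", {
  res_small <- gubs_compile(goal, lib, gubs_config(seed = 1))
  expect_identical(res_small$stats$stage, "exhaustive")
  expect_length(res_small$solutions, 1L)
  inst <- bench_generate(bench_config(
    n_components = 20, n_goal_rules = 4, n_variables = 2, n_constants = 3,
    seed = 5))
  res_ga <- gubs_compile(inst$goal, inst$library, gubs_config(seed = 5))
  expect_identical(res_ga$stats$stage, "evolutionary")
  expect_gt(length(res_ga$solutions), 0L)
})

test_that("GA solutions are sound: the exhaustive path accepts them", {
  # libraries small enough for both paths: every GA solution must be in
  # the exhaustive solution set (no spurious solutions)
  for (seed in c(3, 8, 21)) {
    inst <- bench_generate(bench_config(
      n_components = 6, n_goal_rules = 3, n_variables = 2, n_constants = 2,
      seed = seed))
    exh <- gubs_compile(inst$goal, inst$library,
                        gubs_config(seed = seed, exhaustive_threshold = 12))
    ga <- gubs_compile(inst$goal, inst$library,
                       gubs_config(seed = seed, exhaustive_threshold = 0,
                                   stop_on_success = FALSE,
                                   generations = 15))
    expect_identical(exh$stats$stage, "exhaustive")
    expect_identical(ga$stats$stage, "evolutionary")
    expect_true(all(pipeline_keys(ga) %in% pipeline_keys(exh)))
    expect_gt(length(ga$solutions), 0L)
  }
})

test_that("compile reports reproducibly under a fixed seed", {
  inst <- bench_generate(bench_config(
    n_components = 20, n_goal_rules = 4, n_variables = 2, n_constants = 3,
    seed = 9))
  r1 <- gubs_compile(inst$goal, inst$library, gubs_config(seed = 3))
  r2 <- gubs_compile(inst$goal, inst$library, gubs_config(seed = 3))
  expect_identical(pipeline_keys(r1), pipeline_keys(r2))
  expect_identical(r1$stats$generations, r2$stats$generations)
})

test_that("an unsatisfiable goal raises a diagnosis naming the orphan rule", {
  bad <- parse_program(c("g1 o-> !g2", "Missing o-> !g1"))
  err <- tryCatch(gubs_compile(bad, lib, cfg), condition = function(e) e)
  expect_s3_class(err, "gubsc_no_solution")
  expect_match(conditionMessage(err), "Missing o-> !g1", fixed = TRUE)
  # the empty goal compiles trivially
  res <- gubs_compile(gubs_program(), lib, cfg)
  expect_length(res$solutions, 1L)
  expect_length(res$solutions[[1]]$components, 0L)
})

test_that("solutions come out fitness-ordered (fewest components first)", {
  toy_lib <- gubs_library(list(
    OneStop = parse_program(c("A o-> !Hub", "B o-> !Hub")),
    L1 = parse_program("A o-> !Hub"),
    L2 = parse_program("B o-> !Hub")))
  toy_goal <- parse_program(c("v o-> !Hub", "w o-> !Hub"))
  res <- gubs_compile(toy_goal, toy_lib, gubs_config(seed = 1))
  sizes <- vapply(res$solutions, function(r) length(r$component_set), 0L)
  expect_true(all(diff(sizes) >= 0))
  expect_identical(res$solutions[[1]]$component_set, "OneStop")
})
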