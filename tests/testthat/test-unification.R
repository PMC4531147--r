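# Substitutions, rule unification, full ACI-unification, the synthesis
# calculus steps and the brute-force oracle.

fx <- gubs_fixtures()
goal <- fx$repressilator_goal
lib <- fx$repressilator_lib5
s0 <- substitution(forbidden = constants_of(goal))

test_that("substitutions are injective and never map into goal constants", {
  expect_error(substitution(c(g1 = "CI", g2 = "CI")), "injective")
  expect_error(substitution(c(g1 = "TetR_lite"), forbidden = "TetR_lite"),
               "goal constant")
  s <- gubsc:::subst_extend(s0, "g1", "CI")
  expect_identical(unname(s$map["g1"]), "CI")
  expect_null(gubsc:::subst_extend(s, "g2", "CI"))          # injectivity
  expect_null(gubsc:::subst_extend(s, "g2", "TetR_lite"))   # freshness
  expect_identical(gubsc:::subst_extend(s, "g1", "CI"), s)  # idempotent
  expect_null(gubsc:::subst_extend(s, "g1", "LacI"))        # conflict
})

test_that("unify_rule binds variables to the component's constants", {
  p1 <- goal$rules[[1]]                      # g1 o-> !g2
  q2 <- lib$components$Q2$rules[[1]]         # CI o-> !LacI
  out <- unify_rule(p1, q2, s0)
  expect_length(out, 1L)
  expect_identical(unname(out[[1]]$map[c("g1", "g2")]), c("CI", "LacI"))
})

test_that("unify_rule respects prior bindings and reports failure empty", {
  p3 <- goal$rules[[3]]                      # TetR_lite o-> !g1
  q4 <- lib$components$Q4$rules[[1]]         # TetR_lite o-> !GFP
  s_ci <- gubsc:::subst_extend(s0, "g1", "CI")
  expect_length(unify_rule(p3, q4, s_ci), 0L)   # g1 cannot be unified
  expect_length(unify_rule(p3, q4, s0), 1L)     # unconstrained: g1 -> GFP
  # ground identical rules unify with the substitution unchanged
  g <- parse_program("LacI o-> !TetR_lite")$rules[[1]]
  out <- unify_rule(g, g, s0)
  expect_length(out, 1L)
  expect_length(out[[1]]$map, 0L)
  # kind mismatch is fatal
  gn <- causal_rule("normal", g$cause, g$effect)
  expect_length(unify_rule(gn, g, s0), 0L)
})

test_that("aci_unify resolves (Q2,Q1,Q3) uniquely and rejects (Q2,Q1,Q4)", {
  ok <- aci_unify(goal, c("Q2", "Q1", "Q3"), lib)
  expect_length(ok, 1L)
  expect_identical(unname(ok[[1]]$substitution$map[c("g1", "g2")]),
                   c("CI", "LacI"))
  expect_identical(ok[[1]]$component_set, c("Q1", "Q2", "Q3"))
  expect_length(aci_unify(goal, c("Q2", "Q1", "Q4"), lib), 0L)
})

test_that("a ground goal textually contained in a tuple unifies with empty sigma", {
  ground <- parse_program(c("LacI o-> !TetR_lite", "CI o-> !LacI"))
  out <- aci_unify(ground, c("Q1", "Q2"), lib)
  expect_length(out, 1L)
  expect_length(out[[1]]$substitution$map, 0L)
})

test_that("apply_inst instantiates components and demands observability", {
  q1 <- lib$components$Q1
  expect_true(program_equal(apply_inst(q1, substitution()), q1))
  # an infeasible instance is rejected
  bad <- parse_program("E o-> E")
  bad <- gubs_program(rules = bad$rules,
                      spots = list(observation_spot("e", lit("E"))))
  expect_error(apply_inst(bad), "not observable")
})

test_that("assemble merges compatible partial syntheses", {
  r_p1 <- aci_unify(gubs_program(rules = goal$rules[1]), "Q2", lib)[[1]]
  r_p2 <- aci_unify(gubs_program(rules = goal$rules[2]),
                    "Q1", lib)[[1]]
  merged <- assemble(r_p1, r_p2, lib)
  expect_identical(sort(merged$components), c("Q1", "Q2"))
  expect_identical(unname(merged$substitution$map[c("g1", "g2")]),
                   c("CI", "LacI"))
  # commutative after canonicalization
  merged2 <- assemble(r_p2, r_p1, lib)
  expect_identical(merged$component_set, merged2$component_set)
  expect_identical(gubsc:::subst_key(merged$substitution),
                   gubsc:::subst_key(merged2$substitution))
  # idempotent via contraction
  again <- assemble(r_p1, r_p1, lib)
  expect_identical(again$component_set, r_p1$component_set)
  expect_true(program_equal(again$assembly, r_p1$assembly))
})

test_that("assemble rejects substitution conflicts", {
  p1_only <- gubs_program(rules = goal$rules[1])
  r_a <- aci_unify(p1_only, "Q2", lib)[[1]]    # g1 -> CI,  g2 -> LacI
  r_b <- aci_unify(p1_only, "Q5", lib)         # g1 -> AraC, g2 -> GFP
  expect_length(r_b, 1L)
  expect_error(assemble(r_a, r_b[[1]], lib), "substitution conflict")
})

test_that("no returned substitution maps a variable to a goal constant", {
  # regression on the printed eliminations: TetR_lite may substitute
  # neither g1 nor g2 in any tuple over the whole library
  m <- associate(goal, lib)
  for (tuple in candidate_subsets(goal, lib, m,
                                  agent_filter = FALSE)$tuples) {
    for (r in aci_unify(goal, tuple, lib))
      expect_false("TetR_lite" %in% r$substitution$map)
  }
})

test_that("the oracle finds the single repressilator solution", {
  orc <- brute_force_oracle(goal, lib)
  expect_length(orc, 1L)
  expect_identical(orc[[1]]$components, c("Q1", "Q2", "Q3"))
  expect_identical(orc[[1]]$sigma[c("g1", "g2")],
                   c(g1 = "CI", g2 = "LacI"))
})

test_that("the oracle handles the empty goal and symmetric solutions", {
  empty <- brute_force_oracle(gubs_program(), lib)
  expect_length(empty, 1L)
  expect_length(empty[[1]]$tuple, 0L)
  # two interchangeable constants give two solutions
  toy_lib <- gubs_library(list(
    T1 = parse_program("A o-> !Hub"),
    T2 = parse_program("B o-> !Hub")))
  toy_goal <- parse_program("v o-> !Hub")
  orc <- brute_force_oracle(toy_goal, toy_lib)
  expect_identical(oracle_keys(orc), c("T1|v>A", "T2|v>B"))
  res <- gubs_compile(toy_goal, toy_lib, gubs_config(seed = 1))
  expect_identical(pipeline_keys(res), oracle_keys(orc))
})

test_that("pipeline and oracle agree exactly on random instances", {
  shapes <- list(c(4, 3, 2, 2), c(5, 4, 3, 2), c(5, 2, 1, 3), c(3, 3, 0, 3))
  for (seed in 1:40) {
    cc <- shapes[[1 + (seed %% 4)]]
    inst <- bench_generate(bench_config(
      n_components = cc[1], n_goal_rules = cc[2], n_variables = cc[3],
      n_constants = cc[4], seed = seed))
    res <- gubs_compile(inst$goal, inst$library, gubs_config(seed = seed))
    orc <- brute_force_oracle(inst$goal, inst$library)
    expect_identical(pipeline_keys(res), oracle_keys(orc))
    expect_gt(length(orc), 0L)  # solvable by construction
  }
})
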