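# Histories, satisfaction of the three causal primitives, observability,
# behavioural inclusion and the subsumption chain.

test_that("the six-instant trace collapses to the three-milestone history", {
  h <- extract_history(eq1_trace(), chronological_division("1-2,3-5,6-6"))
  expect_identical(world_tokens(h),
                   list("G(Low)", "G(Mid)", "G(High)"))
})

test_that("trivial and per-instant divisions behave as identity bounds", {
  tr <- eq1_trace()
  h1 <- extract_history(tr, "1-6")
  expect_identical(world_tokens(h1),
                   list(c("G(High)", "G(Low)", "G(Mid)")))
  h6 <- extract_history(tr, "1-1,2-2,3-3,4-4,5-5,6-6")
  expect_length(h6$worlds, 6L)
  expect_identical(world_tokens(h6)[[1]], "G(Low)")
  expect_identical(world_tokens(h6)[[6]], "G(High)")
})

test_that("malformed divisions are rejected", {
  tr <- eq1_trace()
  expect_error(extract_history(tr, "1-2,3-9"), "exceeds trace length")
  expect_error(chronological_division("3-5,1-2"), "consecutive|start")
  expect_error(chronological_division("1-2,4-5"), "consecutive")
  expect_error(chronological_division("2-1"), "out of order")
  expect_error(gubs_trace(list(list(lit("A"), lit("A", "absent")))),
               "negation")
})

test_that("satisfaction implements the three primitive readings", {
  # persistent: cause strictly earlier and co-present
  expect_true(as.logical(satisfies(hw(c("C"), c("C", "E")),
                                   one_rule("persistent"))))
  expect_false(as.logical(satisfies(hw(c("C"), c("E"), c("E")),
                                     one_rule("persistent"))))
  # normal: cause strictly earlier; order violations fail
  expect_false(as.logical(satisfies(hw(c("E"), c("C")), one_rule("normal"))))
  expect_true(as.logical(satisfies(hw(c("C"), c("E")), one_rule("normal"))))
  # remnant: effect persists one step or cause occurred earlier;
  # a first-world effect needs the cause alongside it
  expect_true(as.logical(satisfies(hw(c("C"), c("E"), c("E")),
                                   one_rule("remnant"))))
  expect_true(as.logical(satisfies(hw(c("C", "E")), one_rule("remnant"))))
  expect_false(as.logical(satisfies(hw(c("E")), one_rule("remnant"))))
})

test_that("observation spots and failing rules are reported item by item", {
  p <- gubs_program(rules = list(causal_rule("normal", lit("C"), lit("E"))),
                    spots = list(observation_spot("seen", lit("E")),
                                 observation_spot("missing", lit("Z"))))
  v <- satisfies(hw(c("C"), c("E")), p)
  expect_false(as.logical(v))
  rep <- attr(v, "report")  # rules first, then spots sorted by label
  expect_identical(rep$item[2:3], c("obs_missing", "obs_seen"))
  expect_identical(rep$satisfied, c(TRUE, FALSE, TRUE))
})

test_that("context conjuncts gate satisfaction; compartments localize atoms", {
  p <- parse_program(c("[K]{", "  C -> E", "}"))
  # effect without the context agent ever present: violated
  expect_false(as.logical(satisfies(hw(c("C"), c("E")), p)))
  expect_true(as.logical(satisfies(hw(c("C", "K"), c("E")), p)))
  # a compartment-scoped rule does not see bare top-level atoms
  q <- parse_program(c("M{", "  C -> E", "}"))
  expect_true(as.logical(satisfies(hw(c("C"), c("E")), q)))  # vacuous
})

test_that("numeric qualifiers: points inside intervals satisfy them", {
  p <- one_rule("normal")
  p_int <- gubs_program(rules = list(causal_rule(
    "normal", list(lit("C")),
    list(state_literal("E", qualifier = gubsc:::qual_interval(0.1, 0.4))))))
  h_in <- gubs_history(list(list(lit("C")), list(
    state_literal("E", qualifier = gubsc:::qual_point(0.3)))))
  h_out <- gubs_history(list(list(
    state_literal("E", qualifier = gubsc:::qual_point(0.7))), list(lit("C"))))
  expect_true(as.logical(satisfies(h_in, p_int)))
  # E(0.7) never matches E[0.1,0.4]; the rule is vacuous there
  expect_true(as.logical(satisfies(h_out, p_int)))
})

test_that("the R and C++ satisfaction engines agree on random cases", {
  set.seed(42)
  for (rep in 1:40) {
    inst <- bench_generate(bench_config(
      n_components = 3, n_goal_rules = 3, n_variables = 0, n_constants = 3,
      seed = rep))
    p <- inst$library$components[[1]]
    atoms <- c("P01", "P02", "P03")
    h <- gubs_history(lapply(seq_len(1L + rep %% 4L), function(i) {
      picked <- atoms[stats::runif(3) < 0.5]
      lapply(picked, lit)
    }))
    expect_identical(as.logical(satisfies(h, p, engine = "r")),
                     as.logical(satisfies(h, p, engine = "cpp")))
  }
})

test_that("subsumption chain: persistent => normal => remnant up to 6 worlds", {
  expect_true(as.logical(subsumption_check("persistent", "normal", 6L)))
  expect_true(as.logical(subsumption_check("normal", "remnant", 6L)))
  expect_true(as.logical(subsumption_check("persistent", "remnant", 6L)))
  for (k in c("normal", "persistent", "remnant"))
    expect_true(as.logical(subsumption_check(k, k, 4L)))
})

test_that("remnant is strictly weaker: a separating witness exists", {
  res <- subsumption_check("remnant", "persistent", 3L)
  expect_false(as.logical(res))
  wit <- attr(res, "witness")
  expect_false(is.null(wit))
  # the witness really does separate the two kinds
  h <- gubs_history(lapply(wit, function(w)
    if (length(w)) lapply(w, lit) else list()))
  expect_true(as.logical(satisfies(h, one_rule("remnant"))))
  expect_false(as.logical(satisfies(h, one_rule("persistent"))))
  expect_false(as.logical(subsumption_check("remnant", "normal", 4L)))
})

test_that("observability: empty program, witnesses, and infeasible spots", {
  expect_true(as.logical(observable(gubs_program())))
  # repression rule: the witness keeps the repressed agent initially on
  p <- parse_program("A o-> !B")
  ob <- observable(p, bound = 4L)
  expect_true(as.logical(ob))
  wit <- attr(ob, "witness")
  h <- gubs_history(lapply(wit, function(w)
    if (length(w)) lapply(w, lit) else list()))
  expect_true(as.logical(satisfies(h, p)))
  # a full strong-inhibition pair is infeasible: its two halves constrain
  # the first world in complementary ways (the repressed agent can start
  # neither present nor absent without an unexplained effect)
  expect_false(as.logical(observable(expand_macros(parse_program("A -- B")),
                                     bound = 4L)))
  # self-dependent persistent effect: E would need an earlier E, so no
  # world can ever display it and the spot is infeasible at any bound
  q <- gubs_program(rules = list(causal_rule("persistent", lit("E"),
                                             lit("E"))),
                    spots = list(observation_spot("e", lit("E"))))
  expect_false(as.logical(observable(q, bound = 5L)))
})

test_that("observability requires ground input", {
  expect_error(observable(parse_program("v -> !A")), "ground")
})

test_that("behavioural inclusion is reflexive and follows the chain", {
  fx <- gubs_fixtures()
  lam <- expand_macros(fx$lambda_switch)
  for (p in list(one_rule("normal"), one_rule("persistent"))) {
    expect_true(as.logical(behaviourally_includes(p, p, bound = 4L)))
  }
  expect_true(as.logical(behaviourally_includes(
    one_rule("persistent"), one_rule("normal"), bound = 4L)))
  expect_false(as.logical(behaviourally_includes(
    one_rule("remnant"), one_rule("persistent"), bound = 4L)))
  cx <- attr(behaviourally_includes(one_rule("remnant"),
                                    one_rule("persistent"), bound = 4L),
             "counterexample")
  expect_false(is.null(cx))
})

test_that("inclusion is transitive on a spot-checked chain", {
  a <- one_rule("persistent")
  b <- one_rule("normal")
  c <- one_rule("remnant")
  expect_true(as.logical(behaviourally_includes(a, b, bound = 5L)))
  expect_true(as.logical(behaviourally_includes(b, c, bound = 5L)))
  expect_true(as.logical(behaviourally_includes(a, c, bound = 5L)))
})
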