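# Library reading/writing (XML and JSON) and the built-in fixtures.

test_that("the shipped XML and JSON libraries load identically", {
  x <- read_library(system.file("extdata", "repressilator_lib5_synthetic.xml",
                                package = "gubsc"))
  j <- read_library(system.file("extdata",
                                "repressilator_lib5_synthetic.json",
                                package = "gubsc"))
  expect_identical(names(x$components), names(j$components))
  for (nm in names(x$components))
    expect_true(program_equal(x$components[[nm]], j$components[[nm]]))
  # and both match the built-in fixture
  fx <- gubs_fixtures()$repressilator_lib5
  for (nm in names(fx$components))
    expect_true(program_equal(x$components[[nm]], fx$components[[nm]]))
})

test_that("libraries round-trip through both formats", {
  fx <- gubs_fixtures()$repressilator_lib5
  for (fmt in c("xml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_library(fx, path)
    back <- read_library(path)
    expect_identical(names(back$components), names(fx$components))
    for (nm in names(fx$components))
      expect_true(program_equal(back$components[[nm]], fx$components[[nm]]))
    unlink(path)
  }
})

test_that("a generated 30-component library round-trips, scopes included", {
  inst <- bench_generate(bench_config(
    n_components = 30, n_goal_rules = 5, n_variables = 2, n_constants = 4,
    seed = 2))
  lib <- inst$library
  # add a scoped component to exercise context/compartment serialization
  scoped <- parse_program(c("M{", " [K]{", "  A -> !B", " }", "}"))
  lib <- gubs_library(c(lib$components, list(Scoped = scoped)))
  for (fmt in c("xml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_library(lib, path)
    back <- read_library(path)
    for (nm in names(lib$components))
      expect_true(program_equal(back$components[[nm]],
                                lib$components[[nm]]))
    unlink(path)
  }
})

test_that("empty and malformed library documents are handled", {
  path <- tempfile(fileext = ".xml")
  writeLines('<library version="1"></library>', path)
  expect_length(read_library(path)$components, 0L)
  writeLines('<library><component><gubs>A -> !B</gubs></component></library>',
             path)
  expect_error(read_library(path), "schema|name")
  writeLines(c('<library version="1">',
               '<component name="Q1"><gubs>A -> !B</gubs></component>',
               '<component name="Q1"><gubs>C -> !D</gubs></component>',
               '</library>'), path)
  expect_error(read_library(path), "duplicate component name")
  writeLines(c('<library version="1">',
               '<component name="Q1"><gubs>A -> </gubs></component>',
               '</library>'), path)
  expect_error(read_library(path), "component 'Q1'")
  unlink(path)
  jpath <- tempfile(fileext = ".json")
  writeLines('{"schema_version":"1"}', jpath)
  expect_error(read_library(jpath), "components")
  unlink(jpath)
})

test_that("the reconstructed library replays every printed elimination", {
  fx <- gubs_fixtures()
  goal <- fx$repressilator_goal
  lib <- fx$repressilator_lib5
  comps <- function(...) lapply(c(...), function(nm) lib$components[[nm]])
  # (Q1,Q1,*): TetR_lite is used in the goal, so it cannot substitute g2
  expect_false(as.logical(agent_constraints_ok(goal, comps("Q1", "Q1", "Q3"))))
  # (Q3/Q4,Q1,*): same argument for g1
  for (t in list(c("Q3", "Q1", "Q3"), c("Q4", "Q1", "Q3"),
                 c("Q3", "Q1", "Q4"), c("Q4", "Q1", "Q4")))
    expect_false(as.logical(agent_constraints_ok(goal, comps(t))))
  # (Q5,Q1,Q3) and (Q5,Q1,Q4): occurrence counts of fresh constants fail
  expect_false(as.logical(agent_constraints_ok(goal, comps("Q5", "Q1", "Q3"))))
  expect_false(as.logical(agent_constraints_ok(goal, comps("Q5", "Q1", "Q4"))))
  # (Q2,Q1,Q4) survives the agent filter but fails at substitution
  expect_true(as.logical(agent_constraints_ok(goal, comps("Q2", "Q1", "Q4"))))
  expect_length(aci_unify(goal, c("Q2", "Q1", "Q4"), lib), 0L)
  # (Q2,Q1,Q3) succeeds
  expect_length(aci_unify(goal, c("Q2", "Q1", "Q3"), lib), 1L)
})

test_that("the lambda switch fixture expands to four primitive rules", {
  lam <- gubs_fixtures()$lambda_switch
  expect_length(lam$rules, 2L)
  e <- expand_macros(lam)
  expect_length(e$rules, 4L)
  expect_identical(sort(vapply(e$rules, `[[`, "", "kind")),
                   c("normal", "normal", "persistent", "persistent"))
  expect_length(e$spots, 3L)
  # matches the shipped source file
  disk <- read_program(system.file("extdata", "lambda_switch.gubs",
                                   package = "gubsc"))
  expect_true(program_equal(disk, lam))
})

test_that("a lysogenic-path history answers the lambda observation spots", {
  lam <- expand_macros(gubs_fixtures()$lambda_switch)
  # early Cro activity, then CI takes over and Cro drops to low
  h <- gubs_history(list(
    list(state_literal("Cro", qualifier = gubsc:::qual_label("high"))),
    list(state_literal("Cro", qualifier = gubsc:::qual_label("low")),
         state_literal("CI", qualifier = gubsc:::qual_label("low")))))
  v <- satisfies(h, lam)
  rep <- attr(v, "report")
  spot_rows <- rep[rep$type == "spot", ]
  expect_identical(spot_rows$satisfied, c(TRUE, TRUE, TRUE))
})
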