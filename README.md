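# gubsc

Design automation for synthetic gene circuits from *behavioural*
descriptions.  Instead of writing down DNA parts, you write down the
observations that would convince you the circuit works — causal relations
between biological agents — and the compiler selects and assembles
components from a characterized part library whose collective described
behaviour *covers* yours.

## Who this is for

Synthetic biologists and biodesign-automation developers who keep
libraries of characterized parts (each annotated with the behaviour it
was observed to implement) and want to turn a functional specification
into candidate assemblies automatically, with a logical guarantee rather
than ad-hoc keyword matching.

## The model

A program is a set of **causal relations** between state literals of
**agents** (genes, proteins).  Constants (`TetR_lite`) name real parts;
variables (`g1`) abstract over them.  Literals can be negated (`!g2`) and
qualified by activity levels (`Cro(low)`, `LacI[0.1, 0.4]`).  Three
primitive strengths are read counterfactually from the effect over
*linear Kripke models* (histories extracted from experimental traces):

* `c -> e` (normal): whenever `e` is observed, `c` held in some strictly
  earlier world;
* `c o-> e` (persistent): additionally `c` still holds in `e`'s world;
* `c +-> e` (remnant): either `e` already held in the immediately
  preceding world, or `c` occurred earlier.

Every model of a persistent relation satisfies the normal one, which in
turn satisfies the remnant one — the package verifies this chain by
exhaustive bounded enumeration.  Strong inhibition `a -- b` and strong
activation `a -+ b` are macros expanding to pairs of primitives, and
`obs_<label>:: lit` spots name observations any validating history must
exhibit.

Compilation is **behavioural covering**: an assembly `Q` of library
components covers goal `P` under substitution `σ` (variables ↦ library
constants) when every bounded linear model satisfying `Q` satisfies
`P[σ]`.  The pipeline is (1) local causal association of each goal rule
with component rules (five structural conditions), (2) agent occurrence
constraints on candidate tuples (counts per side and polarity), (3)
ACI-unification — backtracking assignment of goal rules to component
rules modulo associativity, commutativity and idempotence of assembly —
with an observability check that the assembly is not infeasible, and,
for large libraries, (4) a directed evolutionary search over
pre-filtered component tuples.

## Worked example

The classic three-gene repressilator ring, with two genes left abstract:

```r
library(gubsc)
fx  <- gubs_fixtures()
fx$repressilator_goal
#> g1 o-> !g2
#> g2 o-> !TetR_lite
#> TetR_lite o-> !g1

res <- gubs_compile(fx$repressilator_goal, fx$repressilator_lib5,
                    gubs_config(seed = 1))
res
#> compilation (exhaustive stage, seed 1): 1 solution(s)
#>   { Q1, Q2, Q3 }  sigma { g1 -> CI, g2 -> LacI }
```

Association admits all five components for the first rule, only `Q1` for
the second and `{Q3, Q4}` for the third, giving ten candidate tuples; the
agent constraints eliminate eight (no fresh constant can stand for `g1`
or `g2` — `TetR_lite` is already used by the goal), unification rejects
`(Q2,Q1,Q4)` because `g1` cannot be bound consistently, and the single
surviving assembly `{Q1, Q2, Q3}` is the LacI ⊣ TetR ⊣ CI ring with
`g1 = CI`, `g2 = LacI`.

Histories can be checked directly:

```r
tr <- read_trace(system.file("extdata", "trace_G.tsv", package = "gubsc"))
extract_history(tr, "1-2,3-5,6-6")
#> w1: {G(Low)}
#> w2: {G(Mid)}
#> w3: {G(High)}
```

A shell front end ships in `inst/cli/gubsc.R`
(`compile`, `check`, `bench`, `validate-lib`), emitting versioned JSON
reports.

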