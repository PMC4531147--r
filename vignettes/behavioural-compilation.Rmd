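---
title: "Behavioural compilation of gene circuits: models, matching and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural compilation of gene circuits: models, matching and search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gubsc)
```

This vignette is the package's own account of its science: the semantics
it assigns to behavioural programs, the matching and search machinery of
the compiler, the choices made where the design was genuinely open, and
what the shipped tests do and do not establish.

## Programs as expected observations

A program does not describe a mechanism; it collects the observations
that would validate a designed function.  Agents are atomic biological
elements; a *constant* (upper-case initial) names a concrete part, a
*variable* (lower-case) abstracts a class of parts that the compiler must
resolve.  An agent's state is by default present/absent; *attributes*
refine it into symbolic activity levels ordered by capacity
(`Cro:{low<high}`), optionally with pairs of incomparable levels
(`a/~b`), and numeric literals give point concentrations (`LacI(0.3)`)
or active ranges (`LacI[0.1, 0.4]`).

Causality is read counterfactually from the effect — "if the effect is
observed, the cause was effective" — which keeps specifications robust
in an open system where an environmental interaction can always preempt
a planned activation.  Three strengths order the scheduling constraint
between cause and effect (normal `->`, persistent `o->`, remnant `+->`),
and two macros (`-+`, `--`) package the common strong
activation/inhibition idioms; contexts `[k]{...}` gate rule blocks on a
stimulus and compartments `Name{...}` make rules spatially local.

## Histories and satisfaction

Validation operates on *histories*: a raw trace (one symbolic event set
per measurement instant) is divided chronologically into periods, and
each period contributes the set of distinct literals observed in it —
intermediate stages and repeated identical events carry no information.
A history is a Kripke model whose accessibility relation is the
successor relation on worlds (a single path).

```{r history}
tr <- read_trace(system.file("extdata", "trace_G.tsv", package = "gubsc"))
extract_history(tr, "1-2,3-5,6-6")
```

Satisfaction is closed-world per world: a positive literal holds iff the
world contains a compatible positive atom, a negated literal iff it
contains none.  A point atom satisfies an interval literal when it lies
inside it; an interval atom when it is contained in it; an unqualified
literal is satisfied by any activity level of its agent.  The rule
readings are:

* **normal** — every world where an effect literal holds has a strictly
  earlier world where the whole cause set holds;
* **persistent** — additionally the cause set holds in the effect's
  world;
* **remnant** — the effect literal held in the immediately preceding
  world, or the cause occurred strictly earlier; an effect in the very
  first world requires the cause alongside it.

Two readings here were genuinely open and deserve their rationale:

* *The remnant disjunction.*  Reading both disjuncts one-step would
  break the strength chain (a model like `({c}, {}, {e})` satisfies the
  normal relation but would fail a one-step remnant).  We read the
  effect-persistence disjunct one-step — that is what distinguishes
  remnant behaviour, an effect lingering from its own recent past — and
  the cause disjunct as the same unbounded "recent past" used by the
  other two kinds.  Under this reading the chain persistent ⇒ normal ⇒
  remnant is a theorem, and the package proves it per bound by
  exhaustive enumeration (`subsumption_check`), producing a concrete
  model separating remnant from persistent.
* *Multi-literal effects are distributive.*  A rule with effect set
  `{e1, e2}` imposes one obligation per effect literal, with the cause
  set conjunctive.  Under the alternative ("the whole effect set holds")
  a component rule with a *larger* effect set would be semantically
  weaker than the goal rule it matches, and compilation could not be
  sound; distributively, both cause-superset and effect-superset matches
  strengthen the assembly, which is exactly what covering needs.

Contexts are satisfied as cause conjuncts (a rule under `[k]` fires only
in histories where `k` accompanies its cause), and compartments
namespace the atom alphabet, so compartment-local rules are judged
against compartment-local observations.

## Bounded model checking

Observability ("the assembly does not produce an infeasible behaviour")
and behavioural inclusion (every model of the assembly satisfies the
substituted goal) quantify over all linear models.  The package
implements both by exhaustive enumeration over all world sequences up to
a bound, over the atom alphabet of the programs involved — bounded, not
full, logical consequence, and documented as such.  The defaults (bound
= number of goal rules + 2; observability bound 3 inside the pipeline)
reflect that every rule needs at most a cause world and an effect world,
plus slack.  Violations of a rule depend only on the prefix up to the
effect's world, so the C++ search prunes a prefix as soon as a rule
fails; for the repression-shaped assemblies the pipeline produces this
cuts the space by orders of magnitude.  Alphabets are capped at 22 atoms
and enumeration at a node budget; exceeding either is an error, never a
silent verdict.

## The compiler

The unit of matching is the causal rule.  Compilation proceeds in
stages, each a necessary condition for the next, so pruning never loses
a solution:

1. **Association.**  A goal rule is locally associated with a component
   rule when the kinds match, every goal constant appears on the same
   side with the same polarity, the component rule's cause and effect
   are at least as large, an injective counterpart assignment exists per
   side, and declared attribute capacities are at least the goal
   agent's.  A goal rule with no associated component dooms the
   compilation, and the diagnosis names it.
2. **Candidate tuples.**  One associated component per goal rule,
   repetitions allowed; the same component may cover several rules.
3. **Agent constraints.**  Occurrence counts per side *and polarity*:
   each goal constant must occur at least as often in the tuple, and
   each goal variable needs a fresh candidate constant — one not used by
   the goal — with at least the variable's occurrence counts and a
   compatible attribute capacity.  The polarity refinement is slightly
   stronger than counting by side alone and remains a necessary
   condition, because unification preserves literal polarity.
4. **ACI-unification.**  Backtracking over, for each goal rule, the
   rules of its slot's component and all substitution extensions;
   substitutions are injective and never map a variable to a goal
   constant (a variable abstracts a part the program did *not* name —
   this is what eliminates eight of the ten repressilator candidates).
   Each complete substitution yields the assembly of the tuple's
   distinct components (duplicates contract), kept only if observable
   and if every goal observation spot is covered by an assembly spot.

Because goal rule *i* consumes a rule of the component in slot *i*, two
goal rules never share one physical rule instance; this is what makes
the count-based agent constraints provably conservative.  The
brute-force oracle used in the tests enumerates all substitutions and
slot assignments directly, with none of the filters, and the test suite
asserts exact solution-set agreement on hundreds of seeded instances.

Results are canonicalized modulo commutativity (component order) and
contraction (duplicates), ordered by fitness — feasibility, rules
covered, then fewest distinct components — and reported with their
derivation (`Inst`/`Cont.`/`Asm.` steps), substitution and assembly
text.  Observability is checked for every intermediate assembly step as
well as the final one (the stricter of the two defensible readings).

## The directed evolutionary search

Exhaustive tuple enumeration is used for libraries of at most 12
components (beyond that the candidate product is rarely tractable); for
larger libraries a genetic algorithm searches the tuple space.  An
individual is a gene vector with one slot per goal rule, each gene
ranging over that rule's association set — the "directed" part, which
excludes obviously non-unifiable choices a priori; individuals violating
the agent constraints are resampled rather than bred.  Fitness is
lexicographic (feasible, rules unified, fewer distinct components), with
the number of unified rules of an infeasible individual defined as the
largest goal-rule subset unifiable under one substitution, found by
capped backtracking (a full-cover probe without skip branches runs
first, so feasible tuples are never misjudged by the cap).

Gene-level search alone sees only local slot fitness, while feasibility
is a *joint* property: all slots must admit one common substitution.
Half of the initial population (and of every restart) is therefore
seeded substitution-first: candidate substitutions are enumerated in
seeded random order (injective, avoiding goal constants, capped by
`sigma_probe`), the goal is grounded under each, and an individual is
built from components whose rules textually cover each slot.  The
enumeration is exponential in the number of variables only — the
dimension along which compilation effort genuinely grows — and
contributes to the same effort counters.  A memetic step additionally
repairs the best infeasible individual each generation by retrying
alternative components for its failing slots.

Defaults, all exposed in `gubs_config`: population 50, tournament 3,
crossover 0.8, mutation 0.1 per gene (raised to 0.5 for slots whose rule
failed to unify in the parent — mutation is aimed at what is broken),
elitism 1, at most 200 generations with restart-around-the-elite after
20 stagnant ones, and a mandatory seed: every run is exactly
reproducible.  Every GA solution is re-verified by the same
ACI-unification and observability checks as the exhaustive path, so the
GA can never emit a solution the exhaustive path would reject;
completeness is not claimed.

## The benchmark generator

`bench_generate` emulates the evaluation protocol: a library of random
components (by default 100) and a goal (by default 10 rules) built by
sampling component rules and abstracting a configured number of
constants into variables — wholly, so an abstracted constant never also
remains in the goal, which preserves the substitution freshness rule and
makes every instance solvable by construction.  Generated rules have
positive causes and negated effects (the repression shape of all the
worked examples); cause sets of size 1–2; kinds uniform over the three
primitives; agent pools capped at 20 constants.  Consequences worth
stating plainly: assemblies of such rules always admit a short
observability witness (a single all-present world), so passing tests say
nothing about observability pruning on activation-heavy libraries, and
the generator's distributions are documented defaults, not a claim of
equivalence to any particular laboratory library.

Search effort is measured in hardware-independent counters (candidate
tuples, unification backtracking nodes, fitness evaluations), never
seconds.  At desk scale the harness crosses 1 and 3 variables with 2 and
6 constants over ten seeds at 100 components and 10 goal rules; mean
effort grows with the variable count and falls with the constant count —
constants restrict the choices available to unification, so more of them
make compilation easier, not harder.

## Numerical and degenerate-input choices

* Duplicate goal rules contract before matching (idempotence), and an
  empty goal compiles to the empty assembly.
* The empty program is observable by convention (a single empty world).
* Qualifiers unify by exact syntactic equality; the containment
  semantics for numeric ranges applies at satisfaction time, not during
  matching.
* Tie-breaks everywhere are lexicographic (component names, substitution
  keys), making all outputs order-deterministic.
* A variable occurring only in observation spots can never be bound and
  is rejected up front with a diagnosis.

One consequence of the strict first-world reading deserves emphasis: an
effect displayed in the very first world of a history has no visible
cause, so it falsifies a normal or persistent relation.  A lone
repression rule `A o-> !B` is therefore observable only through
histories that *start* with `B` still present; and a full
strong-inhibition pair `{A o-> !B, !A -> B}` is infeasible outright,
because its two halves constrain the first world in complementary ways
(`B` can start neither present nor absent without one unexplained
effect).  Macro pairs are therefore specifications of *transitions*: a
history validates them only from a reference world recorded before the
behaviour of interest, which the bounded models here do not represent.
Relaxing the first world would either contradict the strict reading of
"strictly earlier" on order violations or collapse remnant into normal;
we keep the strict reading and state the consequence.

## Known limitations

* Inclusion and observability are bounded checks; a pathological program
  distinguishable only beyond the world bound would be misjudged.  The
  bound is a parameter.
* Attribute-order checking between a variable and its candidate constant
  compares declared capacities (chain lengths and literal labels), not
  arbitrary order embeddings of partially ordered label sets.
* Each history is checked independently; gathering several partial
  histories into one branching model is future work.
* Semantic soundness is asserted exhaustively only where the bounded
  checker is tractable (small alphabets); at benchmark scale solutions
  are re-verified syntactically (unification + observability), not by
  full model enumeration.
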