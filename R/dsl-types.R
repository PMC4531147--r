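# Abstract syntax of the behavioural DSL: agents, attribute declarations,
# state literals, causal rules, scopes, observation spots, programs.
# All objects are plain lists with a class attribute; constructors
# canonicalize set-valued fields so that structural equality is identical().

AGENT_NAME_RE <- "^[A-Za-z][A-Za-z0-9_]*$"

#' Create an agent reference
#'
#' Agents are the atomic biological elements of a program (genes, proteins,
#' stimuli).  A *constant* names a concrete part and starts with an
#' upper-case letter; a *variable* abstracts over parts and starts with a
#' lower-case letter.  The case rule applies to the first character only, so
#' identifiers such as `TetR_lite` are constants.
#'
#' @param name Identifier; a letter followed by letters, digits or
#'   underscores.
#' @return An object of class `gubs_agent` with fields `name` and `kind`
#'   (`"constant"` or `"variable"`).
#' @examples
#' agent_ref("TetR_lite")$kind  # "constant"
#' agent_ref("g1")$kind         # "variable"
#' @export
agent_ref <- function(name) {
  if (!is.character(name) || length(name) != 1L || !grepl(AGENT_NAME_RE, name))
    stop("invalid agent name: ", deparse(name), call. = FALSE)
  kind <- if (grepl("^[A-Z]", name)) "constant" else "variable"
  structure(list(name = name, kind = kind), class = "gubs_agent")
}

is_constant_agent <- function(a) a$kind == "constant"

# -- qualifiers ---------------------------------------------------------------

qual_none <- function() list(type = "none", value = NULL)

qual_label <- function(label) {
  if (!grepl("^[A-Za-z0-9_]+$", label))
    stop("invalid attribute label: ", deparse(label), call. = FALSE)
  list(type = "label", value = label)
}

qual_point <- function(v) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  list(type = "point", value = as.numeric(v))
}

qual_interval <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.finite(lo), is.finite(hi))
  if (lo > hi)
    stop("interval lower bound exceeds upper bound: [", lo, ", ", hi, "]",
         call. = FALSE)
  list(type = "interval", value = c(as.numeric(lo), as.numeric(hi)))
}

qual_token <- function(q) {
  switch(q$type,
         none     = "",
         label    = paste0("(", q$value, ")"),
         point    = paste0("(", format(q$value, digits = 15), ")"),
         interval = paste0("[", format(q$value[1], digits = 15), ",",
                           format(q$value[2], digits = 15), "]"))
}

#' Create a state literal
#'
#' A literal asserts the presence (or, negated, the absence) of an agent,
#' optionally at a qualified activity level: a symbolic attribute label
#' such as `Cro(low)`, a numeric point such as `LacI(0.3)`, or a closed
#' numeric interval such as `LacI[0.1, 0.4]` meaning the agent is active in
#' that concentration range.
#'
#' @param agent A [agent_ref()] or an agent name.
#' @param polarity `"present"` or `"absent"`.
#' @param qualifier One of `qual_none()`, `qual_label()`, `qual_point()`,
#'   `qual_interval()` (internal helpers); defaults to no qualifier.
#' @return An object of class `gubs_literal`.
#' @export
state_literal <- function(agent, polarity = c("present", "absent"),
                          qualifier = qual_none()) {
  if (is.character(agent)) agent <- agent_ref(agent)
  stopifnot(inherits(agent, "gubs_agent"))
  polarity <- match.arg(polarity)
  stopifnot(is.list(qualifier),
            qualifier$type %in% c("none", "label", "point", "interval"))
  structure(list(agent = agent, polarity = polarity, qualifier = qualifier),
            class = "gubs_literal")
}

negate_literal <- function(l) {
  l$polarity <- if (l$polarity == "present") "absent" else "present"
  l
}

lit_token <- function(l) {
  paste0(if (l$polarity == "absent") "!" else "", l$agent$name,
         qual_token(l$qualifier))
}

# canonical ordering of a literal set; also deduplicates
canon_lit_set <- function(lits) {
  toks <- vapply(lits, lit_token, "")
  lits <- lits[!duplicated(toks)]
  toks <- toks[!duplicated(toks)]
  lits[order(toks, method = "radix")]
}

# -- scope --------------------------------------------------------------------

#' @rdname causal_rule
#' @param contexts List of [agent_ref()]s gating the rules (outermost
#'   first); a rule under context `[k]` is triggered only if `k` is present.
#' @param compartments Character vector of compartment names (outermost
#'   first); compartments make rules spatially local.
#' @export
rule_scope <- function(contexts = list(), compartments = character()) {
  contexts <- lapply(contexts, function(a)
    if (is.character(a)) agent_ref(a) else a)
  stopifnot(all(vapply(contexts, inherits, TRUE, "gubs_agent")),
            is.character(compartments))
  if (length(compartments) &&
      !all(grepl(AGENT_NAME_RE, compartments)))
    stop("invalid compartment name", call. = FALSE)
  structure(list(contexts = contexts, compartments = compartments),
            class = "gubs_scope")
}

scope_is_top <- function(s) !length(s$contexts) && !length(s$compartments)

compartment_path <- function(s) paste(s$compartments, collapse = "/")

RULE_KINDS  <- c("normal", "persistent", "remnant")
MACRO_KINDS <- c("strong_act", "strong_inh")

rule_arrow <- function(kind) {
  switch(kind, normal = "->", persistent = "o->", remnant = "+->",
         strong_act = "-+", strong_inh = "--")
}

#' Create a causal rule
#'
#' A causal relation between a set of cause literals and a set of effect
#' literals, in one of three strengths read counterfactually from the
#' effect:
#' * `normal` (`->`): if an effect is observed, the cause occurred in some
#'   strictly earlier world;
#' * `persistent` (`o->`): additionally the cause is still present in the
#'   effect's world;
#' * `remnant` (`+->`): either the effect already held in the immediately
#'   preceding world, or the cause occurred strictly earlier.
#'
#' The macro kinds `strong_act` (`-+`) and `strong_inh` (`--`) are
#' syntactic sugar eliminated by [expand_macros()].
#'
#' @param kind One of `"normal"`, `"persistent"`, `"remnant"`,
#'   `"strong_act"`, `"strong_inh"`.
#' @param cause,effect Non-empty lists of [state_literal()]s; stored as
#'   canonically ordered sets.
#' @param scope A [rule_scope()]; defaults to top level.
#' @return An object of class `gubs_rule`.
#' @export
causal_rule <- function(kind, cause, effect, scope = rule_scope()) {
  kind <- match.arg(kind, c(RULE_KINDS, MACRO_KINDS))
  if (inherits(cause, "gubs_literal")) cause <- list(cause)
  if (inherits(effect, "gubs_literal")) effect <- list(effect)
  stopifnot(inherits(scope, "gubs_scope"))
  if (!length(cause) || !length(effect))
    stop("causal rule requires a non-empty cause and effect", call. = FALSE)
  stopifnot(all(vapply(cause, inherits, TRUE, "gubs_literal")),
            all(vapply(effect, inherits, TRUE, "gubs_literal")))
  if (kind %in% MACRO_KINDS && (length(cause) != 1L || length(effect) != 1L))
    stop("macro relations take a single cause and a single effect literal",
         call. = FALSE)
  structure(list(kind = kind,
                 cause = canon_lit_set(cause),
                 effect = canon_lit_set(effect),
                 scope = scope),
            class = "gubs_rule")
}

rule_token <- function(r) {
  pre <- character()
  if (length(r$scope$compartments))
    pre <- c(pre, paste0(r$scope$compartments, collapse = "/"), "::")
  if (length(r$scope$contexts))
    pre <- c(pre, vapply(r$scope$contexts,
                         function(a) paste0("[", a$name, "]"), ""))
  paste0(paste(pre, collapse = ""),
         paste(vapply(r$cause, lit_token, ""), collapse = " & "),
         " ", rule_arrow(r$kind), " ",
         paste(vapply(r$effect, lit_token, ""), collapse = " & "))
}

#' Create an attribute declaration
#'
#' Declares the symbolic activity levels of an agent: an ordered chain
#' (`a < b < c`, least capacity first, the order relation meaning "has less
#' capacity than") and/or pairs declared of different, incomparable
#' capacity (`x /~ y`).  A label may not appear both in the chain and in an
#' incomparability pair.
#'
#' @param agent An [agent_ref()] or name.
#' @param chain Character vector of labels, least first; no duplicates.
#' @param unequal List of length-2 character vectors (unordered pairs).
#' @return An object of class `gubs_attrdecl`.
#' @export
attribute_decl <- function(agent, chain = character(), unequal = list()) {
  if (is.character(agent)) agent <- agent_ref(agent)
  stopifnot(inherits(agent, "gubs_agent"), is.character(chain))
  if (anyDuplicated(chain))
    stop("duplicate label in attribute chain of ", agent$name, call. = FALSE)
  unequal <- lapply(unequal, function(p) {
    stopifnot(is.character(p), length(p) == 2L)
    sort(p)
  })
  if (length(unequal)) {
    keys <- vapply(unequal, paste, "", collapse = "\r")
    unequal <- unequal[order(keys, method = "radix")]
    unequal <- unequal[!duplicated(vapply(unequal, paste, "", collapse = "\r"))]
    overlap <- intersect(chain, unlist(unequal))
    if (length(overlap))
      stop("label(s) ", paste(overlap, collapse = ", "),
           " of ", agent$name, " appear both in the capacity chain and in ",
           "an incomparability pair", call. = FALSE)
  }
  structure(list(agent = agent, chain = chain, unequal = unequal),
            class = "gubs_attrdecl")
}

decl_labels <- function(d) unique(c(d$chain, unlist(d$unequal)))

# number of declared attributes of an agent (0 if undeclared)
declared_attr_count <- function(name, declarations) {
  d <- declarations[[name]]
  if (is.null(d)) 0L else length(decl_labels(d))
}

#' Create an observation spot
#'
#' A labelled literal that any validating experimental history must
#' exhibit: observation spots describe effects that must necessarily be
#' fulfilled along a trace.
#'
#' @param label Identifier, unique within a program.
#' @param observed A [state_literal()].
#' @return An object of class `gubs_spot`.
#' @export
observation_spot <- function(label, observed) {
  if (!grepl("^[A-Za-z0-9_]+$", label))
    stop("invalid observation spot label: ", deparse(label), call. = FALSE)
  stopifnot(inherits(observed, "gubs_literal"))
  structure(list(label = label, observed = observed), class = "gubs_spot")
}

#' Create a program
#'
#' A program is a set of attribute declarations, a sequence of causal
#' rules (each carrying its context/compartment scope) and a set of
#' observation spots.  Programs describe both design goals and the
#' behaviour of individual library components.
#'
#' @param declarations List of [attribute_decl()]s (at most one per agent).
#' @param rules List of [causal_rule()]s; order is preserved.
#' @param spots List of [observation_spot()]s with unique labels.
#' @return An object of class `gubs_program`.
#' @export
gubs_program <- function(declarations = list(), rules = list(),
                         spots = list()) {
  stopifnot(all(vapply(declarations, inherits, TRUE, "gubs_attrdecl")),
            all(vapply(rules, inherits, TRUE, "gubs_rule")),
            all(vapply(spots, inherits, TRUE, "gubs_spot")))
  dn <- vapply(declarations, function(d) d$agent$name, "")
  if (anyDuplicated(dn))
    stop("duplicate attribute declaration for agent ",
         dn[duplicated(dn)][1], call. = FALSE)
  declarations <- declarations[order(dn, method = "radix")]
  names(declarations) <- sort(dn, method = "radix")
  sn <- vapply(spots, function(s) s$label, "")
  if (anyDuplicated(sn))
    stop("duplicate observation spot label ", sn[duplicated(sn)][1],
         call. = FALSE)
  spots <- spots[order(sn, method = "radix")]
  names(spots) <- sort(sn, method = "radix")
  p <- structure(list(declarations = declarations, rules = rules,
                      spots = spots), class = "gubs_program")
  validate_program(p)
}

# Program invariant: a constant agent carrying a symbolic label in some
# literal must have a declaration listing that label.
validate_program <- function(p) {
  for (l in program_literals(p)) {
    if (l$qualifier$type == "label" && is_constant_agent(l$agent)) {
      d <- p$declarations[[l$agent$name]]
      if (is.null(d) || !(l$qualifier$value %in% decl_labels(d)))
        stop("undeclared attribute label '", l$qualifier$value,
             "' on constant agent ", l$agent$name, call. = FALSE)
    }
  }
  p
}

# every literal of the program, including observation spots
program_literals <- function(p) {
  out <- list()
  for (r in p$rules) out <- c(out, r$cause, r$effect)
  for (s in p$spots) out <- c(out, list(s$observed))
  out
}

# agents occurring in literals or as contexts
program_agents <- function(p) {
  ag <- lapply(program_literals(p), `[[`, "agent")
  for (r in p$rules) ag <- c(ag, r$scope$contexts)
  ag
}

#' Variable agents of a program
#'
#' @param p A [gubs_program()].
#' @return Sorted character vector of the names of all variable agents
#'   occurring in any literal (or context) of `p`; each counted once.
#' @export
variables_of <- function(p) {
  ag <- program_agents(p)
  sort(unique(vapply(ag[!vapply(ag, is_constant_agent, TRUE)],
                     `[[`, "", "name")), method = "radix")
}

#' @rdname variables_of
#' @return `constants_of()`: sorted character vector of constant agent names.
#' @export
constants_of <- function(p) {
  ag <- program_agents(p)
  sort(unique(vapply(ag[vapply(ag, is_constant_agent, TRUE)],
                     `[[`, "", "name")), method = "radix")
}

#' @rdname variables_of
#' @return `is_ground()`: `TRUE` if the program has no variable agents.
#' @export
is_ground <- function(p) length(variables_of(p)) == 0L

has_macros <- function(p)
  any(vapply(p$rules, function(r) r$kind %in% MACRO_KINDS, TRUE))

#' Structural program equality
#'
#' Programs are compared up to the canonical form maintained by the
#' constructors (declarations and spots sorted, literal sets ordered and
#' deduplicated); the rule sequence order is significant.
#'
#' @param a,b Programs.
#' @export
program_equal <- function(a, b) identical(unclass_deep(a), unclass_deep(b))

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.gubs_program <- function(x, ...) {
  cat(serialize_program(x))
  invisible(x)
}

#' @export
print.gubs_rule <- function(x, ...) {
  cat(rule_token(x), "\n")
  invisible(x)
}

#' @export
format.gubs_literal <- function(x, ...) lit_token(x)

#' @export
print.gubs_literal <- function(x, ...) {
  cat(lit_token(x), "\n")
  invisible(x)
}
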