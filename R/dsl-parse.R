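# Concrete line-oriented dialect.
#
#   Cro:{low<high}            attribute declaration (chain and /~ pairs)
#   LHS -> RHS                normal causal rule
#   LHS o-> RHS               persistent causal rule
#   LHS +-> RHS               remnant causal rule
#   A -+ B / A -- B           strong activation / inhibition macros
#   lit & lit                 multi-literal cause or effect
#   !X, X(low), X(0.3), X[0.1,0.4]   literals
#   obs_<label>:: lit         observation spot
#   [k]{ ... }                context block (k an agent)
#   Name{ ... }               compartment block
#   # comment
#
# Rule arrows must be surrounded by whitespace (identifiers may end in
# characters such as "o" that would otherwise be swallowed by "o->").
# The full grammar ships as inst/extdata/gubs-grammar.ebnf.

ARROW_TO_KIND <- c("->" = "normal", "o->" = "persistent", "+->" = "remnant",
                   "-+" = "strong_act", "--" = "strong_inh")

parse_error <- function(lineno, msg)
  stop(sprintf("parse error at line %d: %s", lineno, msg), call. = FALSE)

parse_literal_token <- function(tok, lineno = NA_integer_) {
  m <- regmatches(tok, regexec(
    "^(!?)\\s*([A-Za-z][A-Za-z0-9_]*)\\s*(?:\\(([^()]*)\\)|\\[([^][]*)\\])?$",
    tok))[[1]]
  if (!length(m))
    parse_error(lineno, paste0("malformed literal '", tok, "'"))
  polarity <- if (m[2] == "!") "absent" else "present"
  name <- m[3]
  qual <- qual_none()
  if (nzchar(m[4])) {
    val <- trimws(m[4])
    num <- suppressWarnings(as.numeric(val))
    qual <- if (!is.na(num)) qual_point(num) else qual_label(val)
  } else if (nzchar(m[5])) {
    parts <- trimws(strsplit(m[5], ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (length(nums) != 2L || anyNA(nums))
      parse_error(lineno, paste0("malformed interval in '", tok, "'"))
    if (nums[1] > nums[2])
      parse_error(lineno, paste0("interval bounds out of order in '", tok, "'"))
    qual <- qual_interval(nums[1], nums[2])
  }
  state_literal(agent_ref(name), polarity, qual)
}

parse_literal_set <- function(side, lineno) {
  toks <- trimws(strsplit(side, "&", fixed = TRUE)[[1]])
  if (!length(toks) || any(!nzchar(toks)))
    parse_error(lineno, "empty literal in '&'-joined set")
  lapply(toks, parse_literal_token, lineno = lineno)
}

parse_declaration_body <- function(name, body, lineno) {
  items <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
  items <- items[nzchar(items)]
  chain <- character()
  unequal <- list()
  for (it in items) {
    if (grepl("<", it, fixed = TRUE)) {
      if (length(chain))
        parse_error(lineno, paste0("multiple capacity chains declared for ",
                                   name))
      chain <- trimws(strsplit(it, "<", fixed = TRUE)[[1]])
      if (any(!grepl("^[A-Za-z0-9_]+$", chain)))
        parse_error(lineno, paste0("malformed chain item '", it, "'"))
    } else if (grepl("/~", it, fixed = TRUE)) {
      pair <- trimws(strsplit(it, "/~", fixed = TRUE)[[1]])
      if (length(pair) != 2L || any(!grepl("^[A-Za-z0-9_]+$", pair)))
        parse_error(lineno, paste0("malformed incomparability pair '", it, "'"))
      unequal <- c(unequal, list(pair))
    } else {
      parse_error(lineno, paste0("malformed declaration item '", it, "'"))
    }
  }
  tryCatch(attribute_decl(agent_ref(name), chain, unequal),
           error = function(e) parse_error(lineno, conditionMessage(e)))
}

#' Parse a program from its textual form
#'
#' @param text A single string (possibly multi-line) or a character vector
#'   of lines in the documented dialect.
#' @return A [gubs_program()].  `parse_program(serialize_program(p))` is
#'   structurally identical to `p`.
#' @seealso [serialize_program()], [read_program()]
#' @examples
#' p <- parse_program(c("g1 o-> !g2", "g2 o-> !TetR_lite"))
#' length(p$rules)
#' @export
parse_program <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  declarations <- list()
  rules <- list()
  spots <- list()
  stack <- list()  # each entry: list(type = "context"/"compartment", value)
  current_scope <- function() {
    ctx <- list(); comp <- character()
    for (fr in stack) {
      if (fr$type == "context") ctx <- c(ctx, list(fr$value))
      else comp <- c(comp, fr$value)
    }
    rule_scope(ctx, comp)
  }
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (line == "}") {
      if (!length(stack)) parse_error(i, "unmatched '}'")
      stack[[length(stack)]] <- NULL
      next
    }
    m <- regmatches(line, regexec(
      "^\\[\\s*([A-Za-z][A-Za-z0-9_]*)\\s*\\]\\s*\\{$", line))[[1]]
    if (length(m)) {
      stack <- c(stack, list(list(type = "context", value = agent_ref(m[2]))))
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*\\{(.*)\\}$", line))[[1]]
    if (length(m)) {
      d <- parse_declaration_body(m[2], m[3], i)
      if (!is.null(declarations[[m[2]]]))
        parse_error(i, paste0("duplicate declaration for ", m[2]))
      declarations[[m[2]]] <- d
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z][A-Za-z0-9_]*)\\s*\\{$", line))[[1]]
    if (length(m)) {
      stack <- c(stack, list(list(type = "compartment", value = m[2])))
      next
    }
    m <- regmatches(line, regexec(
      "^obs_([A-Za-z0-9_]+)\\s*::\\s*(.+)$", line))[[1]]
    if (length(m)) {
      lit <- parse_literal_token(trimws(m[3]), i)
      if (!is.null(spots[[m[2]]]))
        parse_error(i, paste0("duplicate observation spot label ", m[2]))
      spots[[m[2]]] <- observation_spot(m[2], lit)
      next
    }
    # causal rule: arrows require surrounding whitespace
    arrow_re <- "\\s(o->|\\+->|-\\+|--|->)\\s"
    hit <- regexpr(arrow_re, line)
    if (hit == -1L)
      parse_error(i, paste0("unrecognized statement '", line, "'"))
    arrow <- trimws(regmatches(line, hit))
    lhs <- substr(line, 1L, hit - 1L)
    rhs <- substr(line, hit + attr(hit, "match.length"), nchar(line))
    if (regexpr(arrow_re, rhs) != -1L)
      parse_error(i, "multiple arrows in one rule")
    kind <- ARROW_TO_KIND[[arrow]]
    cause <- parse_literal_set(lhs, i)
    effect <- parse_literal_set(rhs, i)
    r <- tryCatch(causal_rule(kind, cause, effect, current_scope()),
                  error = function(e) parse_error(i, conditionMessage(e)))
    rules <- c(rules, list(r))
  }
  if (length(stack))
    parse_error(length(lines), "unclosed scope block")
  tryCatch(gubs_program(unname(declarations), rules, unname(spots)),
           error = function(e) stop(conditionMessage(e), call. = FALSE))
}

#' @rdname parse_program
#' @param path Path to a UTF-8 `.gubs` source file.
#' @export
read_program <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_program(readLines(path, encoding = "UTF-8", warn = FALSE))
}

serialize_declaration <- function(d) {
  items <- character()
  if (length(d$chain)) items <- paste(d$chain, collapse = "<")
  if (length(d$unequal))
    items <- c(items, vapply(d$unequal, paste, "", collapse = "/~"))
  paste0(d$agent$name, ":{", paste(items, collapse = ", "), "}")
}

serialize_rule_body <- function(r) {
  paste(paste(vapply(r$cause, lit_token, ""), collapse = " & "),
        rule_arrow(r$kind),
        paste(vapply(r$effect, lit_token, ""), collapse = " & "))
}

#' Serialize a program to its textual form
#'
#' Emits the canonical spelling: declarations first (sorted by agent),
#' then the rules in sequence order with scope blocks (compartments
#' outermost, then contexts), then observation spots (sorted by label).
#'
#' @param p A [gubs_program()].
#' @return A single string; `parse_program()` of it reproduces `p`.
#' @export
serialize_program <- function(p) {
  out <- vapply(p$declarations, serialize_declaration, "")
  i <- 1L
  n <- length(p$rules)
  while (i <= n) {
    sc <- p$rules[[i]]$scope
    j <- i
    while (j < n && identical(unclass_deep(p$rules[[j + 1L]]$scope),
                              unclass_deep(sc))) j <- j + 1L
    openers <- c(if (length(sc$compartments)) paste0(sc$compartments, "{")
                 else character(),
                 vapply(sc$contexts, function(a) paste0("[", a$name, "]{"),
                        ""))
    depth <- length(openers)
    ind <- function(k) strrep("  ", k)
    out <- c(out,
             unlist(lapply(seq_along(openers),
                           function(k) paste0(ind(k - 1L), openers[k]))),
             vapply(i:j, function(k)
               paste0(ind(depth), serialize_rule_body(p$rules[[k]])), ""),
             if (depth) vapply(rev(seq_len(depth)) - 1L,
                               function(k) paste0(ind(k), "}"), ""))
    i <- j + 1L
  }
  out <- c(out, vapply(p$spots, function(s)
    paste0("obs_", s$label, ":: ", lit_token(s$observed)), ""))
  paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
}

#' @rdname serialize_program
#' @param path Output file path.
#' @export
write_program <- function(p, path) {
  writeLines(serialize_program(p), path, useBytes = TRUE)
  invisible(path)
}
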