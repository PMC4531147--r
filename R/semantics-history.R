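# Traces, chronological divisions, histories and linear Kripke models.
#
# A trace is the raw sequence of symbolic observations (one event set per
# measurement instant).  A chronological division groups instants into
# periods; the history keeps, per period, the distinct literals observed --
# intermediate stages and repetitions of identical events are not relevant
# to validation.  A history is read as a Kripke model whose accessibility
# relation is the successor relation on worlds (linearity).

#' Create a symbolic trace
#'
#' @param events List (length >= 1) of lists of [state_literal()]s, one
#'   event set per instant.
#' @return An object of class `gubs_trace`.
#' @export
gubs_trace <- function(events) {
  stopifnot(is.list(events), length(events) >= 1L)
  events <- lapply(events, function(ev) {
    if (inherits(ev, "gubs_literal")) ev <- list(ev)
    stopifnot(all(vapply(ev, inherits, TRUE, "gubs_literal")))
    check_consistent(ev, "trace event")
    canon_lit_set(ev)
  })
  structure(list(events = events), class = "gubs_trace")
}

# no literal together with its negation (same agent and qualifier)
check_consistent <- function(lits, what) {
  pos <- vapply(lits, function(l) {
    l$polarity <- "present"
    lit_token(l)
  }, "")
  pol <- vapply(lits, `[[`, "", "polarity")
  clash <- intersect(pos[pol == "present"], pos[pol == "absent"])
  if (length(clash))
    stop(what, " contains a literal and its negation: ", clash[1],
         call. = FALSE)
  invisible(lits)
}

#' Read a trace from a TSV file
#'
#' One line per instant; tab-separated literal tokens in the DSL syntax
#' (e.g. `G(Low)`).
#'
#' @param path File path.
#' @return A [gubs_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  gubs_trace(lapply(lines, function(ln) {
    toks <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    lapply(toks[nzchar(toks)], parse_literal_token)
  }))
}

#' Create a chronological division
#'
#' A division groups the instants `1..m` of a trace into consecutive
#' closed periods `[a_i, b_i]`: ordered, non-overlapping, gap-free and
#' starting at instant 1.
#'
#' @param periods List of length-2 integer vectors `c(a, b)`, or a string
#'   such as `"1-2,3-5,6-6"`.
#' @return An object of class `gubs_division`.
#' @export
chronological_division <- function(periods) {
  if (is.character(periods)) {
    stopifnot(length(periods) == 1L)
    periods <- lapply(strsplit(periods, ",", fixed = TRUE)[[1]], function(tk) {
      ab <- suppressWarnings(as.integer(strsplit(trimws(tk), "-",
                                                 fixed = TRUE)[[1]]))
      if (length(ab) != 2L || anyNA(ab))
        stop("malformed period '", tk, "'", call. = FALSE)
      ab
    })
  }
  stopifnot(is.list(periods), length(periods) >= 1L)
  periods <- lapply(periods, function(ab) {
    ab <- as.integer(ab)
    stopifnot(length(ab) == 2L, !anyNA(ab))
    if (ab[1] > ab[2])
      stop("period bounds out of order: [", ab[1], ", ", ab[2], "]",
           call. = FALSE)
    ab
  })
  if (periods[[1]][1] != 1L)
    stop("chronological division must start at instant 1", call. = FALSE)
  for (i in seq_along(periods)[-1]) {
    if (periods[[i]][1] != periods[[i - 1L]][2] + 1L)
      stop("periods must be consecutive: [", periods[[i]][1], ", ",
           periods[[i]][2], "] does not follow [", periods[[i - 1L]][1],
           ", ", periods[[i - 1L]][2], "]", call. = FALSE)
  }
  structure(list(periods = periods), class = "gubs_division")
}

#' Create a history (linear Kripke model)
#'
#' @param worlds Non-empty list of lists of [state_literal()]s; each world
#'   must be internally consistent.
#' @return An object of class `gubs_history`.
#' @export
gubs_history <- function(worlds) {
  stopifnot(is.list(worlds), length(worlds) >= 1L)
  worlds <- lapply(worlds, function(w) {
    if (inherits(w, "gubs_literal")) w <- list(w)
    stopifnot(all(vapply(w, inherits, TRUE, "gubs_literal")))
    check_consistent(w, "history world")
    canon_lit_set(w)
  })
  structure(list(worlds = worlds), class = "gubs_history")
}

#' Extract a history from a trace under a chronological division
#'
#' World `i` of the history is the set of distinct literals occurring in
#' the events of period `i`; repetition of identical events within a
#' period is collapsed.
#'
#' @param trace A [gubs_trace()].
#' @param division A [chronological_division()] (or its string form).
#' @return A [gubs_history()] with one world per period.
#' @examples
#' tr <- gubs_trace(lapply(c("G(Low)", "G(Low)", "G(Mid)", "G(Mid)",
#'                           "G(Mid)", "G(High)"),
#'                         function(t) list(gubsc:::parse_literal_token(t))))
#' h <- extract_history(tr, "1-2,3-5,6-6")
#' length(h$worlds)  # 3
#' @export
extract_history <- function(trace, division) {
  stopifnot(inherits(trace, "gubs_trace"))
  if (!inherits(division, "gubs_division"))
    division <- chronological_division(division)
  m <- length(trace$events)
  worlds <- lapply(division$periods, function(ab) {
    if (ab[2] > m)
      stop("division period [", ab[1], ", ", ab[2],
           "] exceeds trace length ", m, call. = FALSE)
    lits <- do.call(c, trace$events[ab[1]:ab[2]])
    tryCatch(check_consistent(canon_lit_set(lits), "merged period world"),
             error = function(e) stop("inconsistent world for period [",
                                      ab[1], ", ", ab[2], "]: ",
                                      conditionMessage(e), call. = FALSE))
    canon_lit_set(lits)
  })
  gubs_history(worlds)
}

#' @export
print.gubs_history <- function(x, ...) {
  for (i in seq_along(x$worlds))
    cat(sprintf("w%d: {%s}\n", i,
                paste(vapply(x$worlds[[i]], lit_token, ""), collapse = ", ")))
  invisible(x)
}
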