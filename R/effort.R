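# Hardware-independent search-effort counters.  Benchmark comparisons use
# these instead of wall-clock time: candidate tuples enumerated,
# unification backtracking nodes, and fitness evaluations.

.gubsc_effort <- new.env(parent = emptyenv())

effort_bump <- function(field, by = 1L) {
  cur <- get0(field, envir = .gubsc_effort, ifnotfound = 0)
  assign(field, cur + as.numeric(by), envir = .gubsc_effort)
  invisible(NULL)
}

#' Search-effort counters
#'
#' The compiler counts candidate tuples enumerated, unification
#' backtracking nodes and fitness evaluations.  These counters are the
#' hardware-independent measure of search effort used by the benchmark
#' harness.
#'
#' @return Named numeric vector `tuples`, `unify_nodes`, `evaluations`,
#'   `total`.
#' @export
effort_counters <- function() {
  v <- c(tuples = get0("tuples", envir = .gubsc_effort, ifnotfound = 0),
         unify_nodes = get0("unify_nodes", envir = .gubsc_effort,
                            ifnotfound = 0),
         evaluations = get0("evaluations", envir = .gubsc_effort,
                            ifnotfound = 0))
  c(v, total = sum(v))
}

#' @rdname effort_counters
#' @export
reset_effort <- function() {
  rm(list = ls(.gubsc_effort), envir = .gubsc_effort)
  invisible(NULL)
}
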