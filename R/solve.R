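# Whole-graph solving: data reduction, per-component dispatch, and merging
# of component solutions into one solution for the full instance.

#' Solve a weighted bi-cluster editing instance
#'
#' Applies the data reduction ([reduce_graph()]), dispatches every
#' remaining component to a solver, and merges the component solutions.
#' Algorithms: `"exact"` runs the branching solver on every component (the
#' heuristic supplies its upper bound); `"heuristic"` runs only the greedy
#' edge-deletion heuristic; `"auto"` runs the heuristic everywhere and
#' additionally the exact solver on components of at most `exact_size_cap`
#' vertices (beyond the cap the branching tree is impractical and the
#' heuristic answer is kept, with a logged note).
#'
#' @param g a [bipartite_graph()] object (any number of components).
#' @param algorithm "auto", "exact" or "heuristic".
#' @param exact_size_cap component size above which "auto"/"exact" fall
#'   back to the heuristic (default 40).
#' @param node_cap,time_limit per-component caps for the exact search.
#' @param quiet suppress per-component progress messages (stderr).
#' @return a [solution][bce_solution]; attribute `"report"` carries the
#'   per-component run report (see [solve_file()]).
#' @export
solve_graph <- function(g, algorithm = c("auto", "exact", "heuristic"),
                        exact_size_cap = 40L, node_cap = Inf,
                        time_limit = Inf, quiet = TRUE) {
  algorithm <- match.arg(algorithm)
  red <- reduce_graph(g)
  rows <- list()
  sols <- list()
  for (s in red$solved) {
    comp <- s$graph
    rows[[length(rows) + 1L]] <-
      report_row(comp, "reduction", s$solution, 0)
    sols[[length(sols) + 1L]] <- s$solution
  }
  for (comp in red$remaining) {
    nv <- length(comp$a) + length(comp$b)
    t0 <- proc.time()[["elapsed"]]
    if (algorithm == "heuristic" ||
        (algorithm %in% c("auto", "exact") && nv > exact_size_cap)) {
      if (algorithm == "exact" && nv > exact_size_cap && !quiet) {
        message(sprintf(
          "component with %d vertices exceeds exact size cap %d; using heuristic",
          nv, exact_size_cap))
      }
      used <- "heuristic"
      sol <- edge_del_main(comp)
    } else {
      used <- "exact"
      sol <- solve_exact(comp, node_cap = node_cap,
                         time_limit = time_limit)
    }
    el <- proc.time()[["elapsed"]] - t0
    if (!quiet) {
      message(sprintf("component |V|=%d solved by %s: cost %.4g%s",
                      nv, used, sol$total_cost,
                      if (isTRUE(sol$optimal)) " (optimal)" else ""))
    }
    rows[[length(rows) + 1L]] <- report_row(comp, used, sol, el)
    sols[[length(sols) + 1L]] <- sol
  }
  merged <- merge_solutions(g, sols)
  attr(merged, "report") <- do.call(rbind, rows)
  merged
}

report_row <- function(comp, used, sol, elapsed) {
  data.frame(vertices = length(comp$a) + length(comp$b),
             edges = sum(adjacency(comp)),
             algorithm = used,
             cost = sol$total_cost,
             optimal = isTRUE(sol$optimal),
             nodes = if (is.null(sol$nodes)) NA_real_ else sol$nodes,
             seconds = elapsed,
             stringsAsFactors = FALSE)
}

merge_solutions <- function(g, sols) {
  edits <- do.call(rbind, c(list(empty_edits()),
                            lapply(sols, function(s) s$edits)))
  sol <- make_solution(g, edits,
                       optimal = all(vapply(sols, function(s)
                         isTRUE(s$optimal), logical(1))),
                       nodes = sum(vapply(sols, function(s)
                         if (is.null(s$nodes) || is.na(s$nodes)) 0
                         else s$nodes, numeric(1))))
  sol
}
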