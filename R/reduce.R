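# Data reduction: preprocessing shared by both solvers. Components that
# are already bi-cliques (including isolated vertices) need no repair and
# leave the instance as zero-cost partial solutions; every remaining
# component contains at least one P4. Runs in time linear in the component
# sizes: each component is checked by comparing its edge count against the
# complete |A| x |B| count, without enumerating P4s.

#' Reduce an instance to its non-transitive components
#'
#' @param g a [bipartite_graph()] object.
#' @return list with `solved`: list of `list(graph, solution)` pairs for
#'   the already-transitive components (empty zero-cost solutions), and
#'   `remaining`: list of components that still contain a P4. Together the
#'   two lists cover every vertex, and the optimum of `g` equals the sum of
#'   the optima of `remaining`.
#' @export
reduce_graph <- function(g) {
  comps <- graph_components(g)
  solved <- list()
  remaining <- list()
  for (comp in comps) {
    na <- length(comp$a)
    nb <- length(comp$b)
    complete <- sum(adjacency(comp)) == na * nb
    if (complete) {
      solved[[length(solved) + 1L]] <-
        list(graph = comp,
             solution = make_solution(comp, empty_edits(), optimal = TRUE))
    } else {
      remaining[[length(remaining) + 1L]] <- comp
    }
  }
  list(solved = solved, remaining = remaining)
}
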