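# Exact fixed-parameter solver: recursive 4-way branching on P4s. Each
# search node resolves the canonical P4 (u, v, w, x) by one of four edits,
# in fixed order: insert ux (pair becomes permanent), or delete uv / wv /
# wx (pair becomes forbidden). Marks make every pair editable at most once
# along a root-to-leaf path, so the tree is finite; with all |weights| > 1
# the tree has at most 4^ceil(k) nodes for optimum cost k.

#' Exact solver for weighted bi-cluster editing
#'
#' Branch-and-bound over the P4 branching tree. The incumbent upper bound
#' is initialized from the greedy heuristic ([edge_del_main()]) and
#' tightened on every improvement, so the search proves optimality of the
#' best solution found. Optional node/time caps make the solver safe on
#' large components: when a cap is hit the best incumbent is returned with
#' `optimal = FALSE` and a warning.
#'
#' @param g a connected [bipartite_graph()] object (split components with
#'   [graph_components()] or use [solve_graph()]).
#' @param incumbent optional starting [solution][bce_solution] (upper
#'   bound); defaults to the heuristic solution.
#' @param node_cap,time_limit maximum search-tree nodes / seconds
#'   (default unlimited).
#' @return a [solution][bce_solution] with `optimal = TRUE` when the tree
#'   was fully explored; `nodes` holds the visited node count.
#' @export
solve_exact <- function(g, incumbent = NULL, node_cap = Inf,
                        time_limit = Inf) {
  if (length(unique(component_membership(g))) > 1L) {
    stop("solve_exact requires a connected graph; split components first",
         call. = FALSE)
  }
  if (is.null(incumbent)) incumbent <- edge_del_main(g)
  st <- fpt_search(g, bound = incumbent$total_cost, node_cap = node_cap,
                   time_limit = time_limit, accept_equal = FALSE)
  if (st$aborted) {
    warning("search budget exhausted; returning best incumbent (non-optimal)",
            call. = FALSE)
  }
  if (is.null(st$edits)) {
    # nothing strictly better than the incumbent: it is optimal
    sol <- incumbent
    sol$optimal <- !st$aborted
    sol$nodes <- st$nodes
    return(sol)
  }
  make_solution(g, st$edits, optimal = !st$aborted, nodes = st$nodes)
}

#' Budgeted branching search
#'
#' Explores the P4 branching tree with a fixed modification budget `k`:
#' returns a minimum-cost solution of cost at most `k` (up to the
#' comparison tolerance), or `NULL` when every branch is pruned, i.e. the
#' instance has no solution within budget.
#'
#' @param g a connected [bipartite_graph()] object.
#' @param k nonnegative modification budget.
#' @param node_cap,time_limit optional search caps.
#' @return a [solution][bce_solution] or `NULL`.
#' @export
branch_search <- function(g, k, node_cap = Inf, time_limit = Inf) {
  stopifnot(k >= 0)
  st <- fpt_search(g, bound = k, node_cap = node_cap,
                   time_limit = time_limit, accept_equal = TRUE)
  if (is.null(st$edits) && st$best_cost > k + g$eps) return(NULL)
  if (is.null(st$edits)) return(NULL)
  make_solution(g, st$edits, optimal = !st$aborted, nodes = st$nodes)
}

# Thin wrapper around the compiled branch-and-bound core. With
# accept_equal = TRUE solutions costing up to bound (+eps) are accepted
# (budget semantics); otherwise only strict improvements over the bound
# are recorded (incumbent semantics).
fpt_search <- function(g, bound, node_cap, time_limit, accept_equal) {
  verts <- sort_lex(c(g$a, g$b))
  in_a <- verts %in% g$a
  ord_side <- ifelse(in_a, 0L, 1L)
  ord_idx <- ifelse(in_a, match(verts, g$a), match(verts, g$b)) - 1L
  res <- fpt_search_cpp(g$w, g$marks, g$eps, bound, accept_equal,
                        node_cap, time_limit,
                        as.integer(ord_side), as.integer(ord_idx))
  edits <- NULL
  listed <- attr(g, "listed")
  if (res$found) {
    if (!length(res$op)) {
      edits <- empty_edits()
    } else {
      idx <- cbind(res$i, res$j)
      edits <- data.frame(
        op = ifelse(res$op == 0L, "insert", "delete"),
        u = g$a[res$i], v = g$b[res$j], cost = res$cost,
        default_weight = res$op == 0L &
          (if (is.null(listed)) FALSE else !listed[idx]),
        stringsAsFactors = FALSE)
    }
  }
  list(edits = edits, best_cost = res$best_cost, nodes = res$nodes,
       aborted = res$aborted)
}
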