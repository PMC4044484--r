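# Brute-force oracle: the obviously-correct optimum for tiny instances,
# used as ground truth by the test-suite. Enumerates every set partition of
# the vertices (restricted-growth strings); the cost of a partition is the
# insertion cost of absent within-block cross pairs plus the deletion cost
# of between-block edges. No pruning on purpose.

#' Exhaustive optimal solution for small graphs
#'
#' Enumerates all partitions of the vertex set into clusters and returns a
#' minimum-cost one as a solution. Blocks whose vertices all lie on one
#' side cost nothing and are split into singletons in the reported
#' clustering. Guarded to at most `max_vertices` vertices (Bell-number
#' blow-up).
#'
#' @param g a [bipartite_graph()] object.
#' @param max_vertices refuse instances larger than this (default 10).
#' @return a [solution][bce_solution] with `optimal = TRUE`.
#' @export
brute_force_optimal <- function(g, max_vertices = 10L) {
  verts <- sort_lex(c(g$a, g$b))
  n <- length(verts)
  if (n > max_vertices) {
    stop("brute_force_optimal refuses graphs with more than ",
         max_vertices, " vertices", call. = FALSE)
  }
  if (n == 0L) return(make_solution(g, empty_edits(), optimal = TRUE))
  adj <- adjacency(g)
  rc <- repair_costs(g)
  # cross pairs in global vertex indexing
  ai <- match(g$a, verts)
  bi <- match(g$b, verts)
  pair_i <- rep(ai, times = length(bi))
  pair_j <- rep(bi, each = length(ai))
  is_edge <- as.vector(adj)
  icost <- ifelse(is_edge, 0, as.vector(rc$ins))   # pay if same block
  dcost <- ifelse(is_edge, as.vector(rc$del), 0)   # pay if split
  parts <- rgs_matrix(n)
  cost <- rep(0, nrow(parts))
  for (p in seq_along(pair_i)) {
    same <- parts[, pair_i[p]] == parts[, pair_j[p]]
    cost <- cost + ifelse(same, icost[p], dcost[p])
  }
  bestrow <- which.min(cost)   # first minimum in enumeration order
  memb <- parts[bestrow, ]
  names(memb) <- verts
  edits <- partition_edits(g, memb)
  sol <- make_solution(g, edits, optimal = TRUE)
  sol
}

# All restricted-growth strings of length n (canonical set partitions).
rgs_matrix <- function(n) {
  m <- matrix(1L, nrow = 1L, ncol = 1L)
  mx <- matrix(1L, nrow = 1L, ncol = 1L)   # running max per row
  for (v in seq_len(n - 1L)) {
    reps <- mx[, 1L] + 1L
    rows <- rep(seq_len(nrow(m)), reps)
    newcol <- unlist(lapply(seq_len(nrow(m)),
                            function(r) seq_len(mx[r, 1L] + 1L)))
    m <- cbind(m[rows, , drop = FALSE], newcol)
    mx <- matrix(pmax(mx[rows, 1L], newcol), ncol = 1L)
  }
  colnames(m) <- NULL
  m
}

# Edits that realize a vertex partition: delete edges between blocks,
# insert missing cross pairs within blocks.
partition_edits <- function(g, memb) {
  adj <- adjacency(g)
  listed <- attr(g, "listed")
  ed <- list()
  for (ia in seq_along(g$a)) {
    for (jb in seq_along(g$b)) {
      same <- memb[[g$a[ia]]] == memb[[g$b[jb]]]
      if (adj[ia, jb] && !same) {
        cost <- if (g$marks[ia, jb] == MARK_PERMANENT) Inf
                else max(0, g$w[ia, jb])
        ed[[length(ed) + 1L]] <-
          data.frame(op = "delete", u = g$a[ia], v = g$b[jb], cost = cost,
                     default_weight = FALSE, stringsAsFactors = FALSE)
      } else if (!adj[ia, jb] && same) {
        cost <- if (g$marks[ia, jb] == MARK_FORBIDDEN) Inf
                else max(0, -g$w[ia, jb])
        ed[[length(ed) + 1L]] <-
          data.frame(op = "insert", u = g$a[ia], v = g$b[jb], cost = cost,
                     default_weight =
                       if (is.null(listed)) FALSE else !listed[ia, jb],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(ed)) return(empty_edits())
  do.call(rbind, ed)
}
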