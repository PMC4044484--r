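# Greedy edge-deletion heuristic. Edge deletions are the hard part of
# bi-cluster editing (they decide the number of resulting bi-cliques), so
# the heuristic places deletions first, scored by how much each deletion
# reduces the graph's deviation from transitivity, and finishes every
# remaining component by inserting the missing pairs of its bi-clique
# closure.

#' Deviation from transitivity D(G)
#'
#' Sum over all P4s of the cost of the cheapest single repair of that P4
#' (the minimum of the three deletion costs and the one insertion cost,
#' i.e. the minimum absolute stored weight over its four pairs). Permanent
#' and forbidden pairs are unrepairable and enter the minimum as +Inf; in
#' particular a P4 whose missing pair is forbidden keeps the minimum over
#' its three finite edge weights. D(G) = 0 iff the graph is transitive.
#'
#' @param g a [bipartite_graph()] object.
#' @return nonnegative numeric.
#' @export
deviation <- function(g) {
  sum(p4_table(g)$mins)
}

# Per-pair repair-cost matrices (shifted scale): deletion cost of current
# edges, insertion cost of current non-edges; locked pairs cost +Inf.
repair_costs <- function(g) {
  list(del = ifelse(g$marks == MARK_PERMANENT, Inf, pmax(0, g$w)),
       ins = ifelse(g$marks == MARK_FORBIDDEN, Inf, pmax(0, -g$w)))
}

# Sum of deviation terms of all quads {u, a2 | v, b2} containing the fixed
# cross pair (ia, jb), under edge indicator adj and repair costs rc, where
# the pair (ia, jb) itself has the given edge status / repair cost.
# Vectorized over the (a2, b2) grid; O(|V|^2).
quad_sum_at <- function(g, adj, rc, ia, jb, pair_edge, pair_cost) {
  na <- length(g$a)
  nb <- length(g$b)
  if (na < 2L || nb < 2L) return(0)
  a2 <- setdiff(seq_len(na), ia)
  b2 <- setdiff(seq_len(nb), jb)
  # pair roles in quad {u=ia, a2 | v=jb, b2}: (ia,jb) fixed, (ia,b2) row
  # vector, (a2,jb) col vector, (a2,b2) matrix
  e_ub <- adj[ia, b2]                      # ia-b2
  e_av <- adj[a2, jb]                      # a2-jb
  e_ab <- adj[a2, b2, drop = FALSE]        # a2-b2
  ne <- outer(e_av, e_ub, "+") + e_ab + pair_edge
  isp4 <- ne == 3L
  if (!any(isp4)) return(0)
  c_ub <- ifelse(e_ub, rc$del[ia, b2], rc$ins[ia, b2])
  c_av <- ifelse(e_av, rc$del[a2, jb], rc$ins[a2, jb])
  c_ab <- ifelse(e_ab, rc$del[a2, b2, drop = FALSE],
                 rc$ins[a2, b2, drop = FALSE])
  m <- pmin(outer(c_av, c_ub, pmin), c_ab, pair_cost)
  sum(m[isp4])
}

#' Transitivity improvement of deleting one edge
#'
#' `Delta(uv) = D(G) - D(G') - s(uv)`, where G' is G with the edge uv
#' removed and marked forbidden. Only P4s whose vertex set contains both u
#' and v change between G and G', so the score is computed from those quads
#' alone.
#'
#' @param g a [bipartite_graph()] object.
#' @param u,v the edge's endpoints (either order; one per side).
#' @return numeric score; higher means deleting this edge repairs more
#'   deviation per unit cost.
#' @export
transitivity_improvement <- function(g, u, v) {
  ij <- pair_index(g, u, v)
  adj <- adjacency(g)
  if (!adj[ij[1L], ij[2L]]) {
    stop("transitivity_improvement requires an existing edge", call. = FALSE)
  }
  if (g$marks[ij[1L], ij[2L]] == MARK_PERMANENT) {
    stop("cannot score deletion of a permanent edge", call. = FALSE)
  }
  delta_of_pair(g, adj, repair_costs(g), ij[1L], ij[2L])
}

delta_of_pair <- function(g, adj, rc, ia, jb) {
  w_uv <- g$w[ia, jb]
  before <- quad_sum_at(g, adj, rc, ia, jb, pair_edge = 1L,
                        pair_cost = rc$del[ia, jb])
  # after deletion the pair is a forbidden non-edge: insertion cost +Inf
  after <- quad_sum_at(g, adj, rc, ia, jb, pair_edge = 0L, pair_cost = Inf)
  before - after - w_uv
}

# Full scoring of all deletable edges; NA where not a candidate.
culprit_scores <- function(g) {
  adj <- adjacency(g)
  rc <- repair_costs(g)
  delta <- matrix(NA_real_, nrow = length(g$a), ncol = length(g$b),
                  dimnames = dimnames(g$w))
  idx <- which(adj & g$marks != MARK_PERMANENT, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    delta[idx[r, 1L], idx[r, 2L]] <-
      delta_of_pair(g, adj, rc, idx[r, 1L], idx[r, 2L])
  }
  delta
}

#' Remove the culprit edge
#'
#' Deletes the edge with the highest [transitivity_improvement()] (ties
#' broken by lexicographic pair order) and marks it forbidden. The first
#' call scores every edge; the scores are cached on the graph and
#' subsequent calls rescore only the edges affected by the deletion.
#'
#' @param g a [bipartite_graph()] object with at least one deletable edge.
#' @return list with `edge` (character c(u, v), sides A/B), `cost` (the
#'   deleted edge's stored weight) and `graph` (with the edge forbidden and
#'   the score cache updated).
#' @export
remove_culprit <- function(g) {
  delta <- attr(g, "delta")
  if (is.null(delta)) delta <- culprit_scores(g)
  cand <- which(!is.na(delta), arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    stop("no deletable edge remains", call. = FALSE)
  }
  best <- max(delta[cand])
  hit <- cand[delta[cand] == best, , drop = FALSE]
  ord <- order(g$a[hit[, 1L]], g$b[hit[, 2L]], method = "radix")
  ia <- hit[ord[1L], 1L]
  jb <- hit[ord[1L], 2L]
  cost <- g$w[ia, jb]
  g2 <- g
  g2$marks[ia, jb] <- MARK_FORBIDDEN
  attr(g2, "delta") <- update_scores(g, g2, delta, ia, jb)
  list(edge = c(g$a[ia], g$b[jb]), cost = cost, graph = g2)
}

# Incremental rescoring after forbidding (ia, jb): edges sharing a vertex
# with the deleted edge are rescored from their quads; any other edge
# (a2, b2) shares exactly one quad {ia, a2 | jb, b2} with the deleted pair,
# so its score is adjusted by that quad's contribution change.
update_scores <- function(g_old, g_new, delta, ia, jb) {
  delta[ia, jb] <- NA_real_
  adj_o <- adjacency(g_old)
  adj_n <- adjacency(g_new)
  rc_o <- repair_costs(g_old)
  rc_n <- repair_costs(g_new)
  na <- length(g_new$a)
  nb <- length(g_new$b)
  touched <- !is.na(delta) & (row(delta) == ia | col(delta) == jb)
  for (idx in which(touched)) {
    i <- row(delta)[idx]
    j <- col(delta)[idx]
    delta[i, j] <- delta_of_pair(g_new, adj_n, rc_n, i, j)
  }
  rest <- which(!is.na(delta) & row(delta) != ia & col(delta) != jb)
  for (idx in rest) {
    i <- row(delta)[idx]
    j <- col(delta)[idx]
    old_term <- quad_term(g_old, adj_o, rc_o, i, j, ia, jb)
    new_term <- quad_term(g_new, adj_n, rc_n, i, j, ia, jb)
    delta[i, j] <- delta[i, j] - old_term + new_term
  }
  delta
}

# Contribution of the single quad {i, ia | j, jb} to Delta(i, j) under the
# given graph state: deviation term of the quad with the edge (i, j)
# present, minus the term with (i, j) forbidden.
quad_term <- function(g, adj, rc, i, j, ia, jb) {
  e2 <- adj[i, jb]
  e3 <- adj[ia, j]
  e4 <- adj[ia, jb]
  c2 <- if (e2) rc$del[i, jb] else rc$ins[i, jb]
  c3 <- if (e3) rc$del[ia, j] else rc$ins[ia, j]
  c4 <- if (e4) rc$del[ia, jb] else rc$ins[ia, jb]
  ne_rest <- e2 + e3 + e4
  before <- if (ne_rest + 1L == 3L) min(rc$del[i, j], c2, c3, c4) else 0
  after <- if (ne_rest == 3L) min(Inf, c2, c3, c4) else 0
  before - after
}

#' Cost of closing a connected graph into a bi-clique
#'
#' Total insertion cost of all missing cross-side pairs; `Inf` if any
#' required pair is forbidden.
#'
#' @param g a connected [bipartite_graph()] object.
#' @return nonnegative numeric, possibly `Inf`.
#' @export
transitive_closure_cost <- function(g) {
  if (length(unique(component_membership(g))) > 1L) {
    stop("transitive_closure_cost requires a connected graph", call. = FALSE)
  }
  adj <- adjacency(g)
  miss <- !adj
  if (!any(miss)) return(0)
  ins <- ifelse(g$marks == MARK_FORBIDDEN, Inf, pmax(0, -g$w))
  sum(ins[miss])
}

closure_edits <- function(g) {
  adj <- adjacency(g)
  idx <- which(!adj, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_edits())
  listed <- attr(g, "listed")
  data.frame(op = "insert", u = g$a[idx[, 1L]], v = g$b[idx[, 2L]],
             cost = ifelse(g$marks[idx] == MARK_FORBIDDEN, Inf,
                           pmax(0, -g$w[idx])),
             default_weight = if (is.null(listed)) FALSE else !listed[idx],
             stringsAsFactors = FALSE)
}

#' Greedy edge-deletion heuristic
#'
#' Solves weighted bi-cluster editing approximately on a connected graph:
#' at each level it compares the cost of closing the component into a
#' single bi-clique against tentatively deleting the current culprit edge
#' (highest transitivity improvement) and recursing on the resulting
#' components, and keeps the cheaper of the two. Deletions stop as soon as
#' they no longer improve the solution; each edge is deleted at most once
#' and never re-inserted. The result is always feasible (P4-free) and its
#' cost bounds the optimum from above.
#'
#' @param g a connected [bipartite_graph()] object.
#' @return a [solution][bce_solution] object with `optimal = FALSE` unless
#'   the graph needed no edits.
#' @export
edge_del_main <- function(g) {
  if (length(unique(component_membership(g))) > 1L) {
    stop("edge_del_main requires a connected graph; split components first",
         call. = FALSE)
  }
  edits <- edge_del_rec(g)
  make_solution(g, edits, optimal = nrow(edits) == 0L)
}

edge_del_rec <- function(g) {
  if (is_transitive(g)) return(empty_edits())
  close_cost <- transitive_closure_cost(g)
  if (!any(adjacency(g) & g$marks != MARK_PERMANENT)) {
    # no deletable edge left: closing is the only repair
    return(closure_edits(g))
  }
  rc <- remove_culprit(g)
  parts <- graph_components(rc$graph)
  sub_edits <- lapply(parts, edge_del_rec)
  del_cost <- rc$cost + sum(vapply(sub_edits, function(e) sum(e$cost),
                                   numeric(1)))
  if (close_cost <= del_cost) {
    closure_edits(g)
  } else {
    del <- data.frame(op = "delete", u = rc$edge[1L], v = rc$edge[2L],
                      cost = rc$cost, default_weight = FALSE,
                      stringsAsFactors = FALSE)
    rbind(del, do.call(rbind, sub_edits))
  }
}
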