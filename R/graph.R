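# Pair-mark states. Marks are mutated only by the solvers: branching locks a
# pair as present (permanent) or absent (forbidden); the heuristic forbids
# deleted edges so they are never re-inserted.
MARK_FREE <- 0L
MARK_PERMANENT <- 1L
MARK_FORBIDDEN <- 2L

#' Construct a weighted bipartite graph
#'
#' Low-level constructor. Weights are on the *shifted* scale: a free pair is
#' an edge iff its stored weight is strictly positive (beyond the comparison
#' tolerance). Most users should call [build_graph()] or [read_edge_tsv()]
#' instead.
#'
#' @param side_a,side_b character vectors of vertex identifiers; the union
#'   must be duplicate-free (a vertex lives on exactly one side).
#' @param weights numeric matrix, `length(side_a)` rows x `length(side_b)`
#'   columns, of shifted similarity weights for every cross-side pair.
#' @param marks integer matrix of the same shape; 0 = free, 1 = permanent,
#'   2 = forbidden.
#' @param eps numeric comparison tolerance for edge presence and costs.
#' @return An object of class `"bcgraph"`: a list with sorted vertex
#'   vectors `$a`, `$b`, the weight matrix `$w`, the mark matrix `$marks`
#'   and the tolerance `$eps`.
#' @seealso [build_graph()], [edges_of()], [is_transitive()]
#' @export
bipartite_graph <- function(side_a, side_b, weights, marks = NULL,
                            eps = 1e-9) {
  side_a <- as.character(side_a)
  side_b <- as.character(side_b)
  if (anyDuplicated(c(side_a, side_b)) > 0L) {
    stop("side conflict: each vertex must appear on exactly one side",
         call. = FALSE)
  }
  oa <- order_lex(side_a)
  ob <- order_lex(side_b)
  na <- length(side_a)
  nb <- length(side_b)
  weights <- matrix(as.numeric(weights), nrow = na, ncol = nb)
  weights <- weights[oa, ob, drop = FALSE]
  if (is.null(marks)) {
    marks <- matrix(MARK_FREE, nrow = na, ncol = nb)
  } else {
    marks <- matrix(as.integer(marks), nrow = na, ncol = nb)
    marks <- marks[oa, ob, drop = FALSE]
  }
  side_a <- side_a[oa]
  side_b <- side_b[ob]
  dimnames(weights) <- list(side_a, side_b)
  dimnames(marks) <- dimnames(weights)
  structure(list(a = side_a, b = side_b, w = weights, marks = marks,
                 eps = eps),
            class = "bcgraph")
}

# C-locale (radix) ordering: the package's single deterministic vertex order.
order_lex <- function(x) order(x, method = "radix")

sort_lex <- function(x) sort(x, method = "radix")

#' Build a graph from weighted edge records
#'
#' Applies the similarity threshold by *shifting*: stored weight =
#' input weight - threshold, so that edge presence is simply
#' "stored weight > 0" and insertion/deletion costs are consistent near the
#' threshold. Cross-side pairs not listed in `records` receive
#' `default_weight` (already on the shifted scale).
#'
#' @param records data.frame (or 3-column matrix) with columns: side-A
#'   vertex, side-B vertex, similarity weight. Sides are assigned by column.
#' @param threshold similarity threshold; input pairs with weight strictly
#'   above it become edges.
#' @param default_weight shifted weight for unlisted cross-side pairs
#'   (negative = assumed dissimilar). Default -1.
#' @param eps comparison tolerance.
#' @return A [bipartite_graph()] object. The attribute `"listed"` is a
#'   logical matrix recording which pairs were present in the input, used to
#'   flag default-weight insertions in solver output.
#' @examples
#' g <- build_graph(data.frame(a = c("P1", "P1"), b = c("G1", "G2"),
#'                             w = c(2, 3)), threshold = 0)
#' edges_of(g)
#' @export
build_graph <- function(records, threshold = 0, default_weight = -1,
                        eps = 1e-9) {
  if (is.matrix(records)) records <- as.data.frame(records,
                                                   stringsAsFactors = FALSE)
  if (ncol(records) < 3L) {
    stop("edge records need 3 columns: vertexA, vertexB, weight",
         call. = FALSE)
  }
  u <- as.character(records[[1L]])
  v <- as.character(records[[2L]])
  wt <- as.numeric(records[[3L]])
  if (any(is.na(wt))) stop("non-numeric weight in edge records",
                           call. = FALSE)
  if (any(u == v)) {
    stop("self-loops are not permitted: ", u[u == v][1L], call. = FALSE)
  }
  both <- intersect(unique(u), unique(v))
  if (length(both)) {
    stop("side conflict: vertex occurs in both columns: ",
         paste(sort_lex(both), collapse = ", "), call. = FALSE)
  }
  key <- paste0(u, "\r", v)
  if (anyDuplicated(key) > 0L) {
    dup <- key[duplicated(key)]
    for (k in unique(dup)) {
      ws <- wt[key == k]
      if (diff(range(ws)) > eps) {
        stop("format error: duplicate pair with conflicting weights: ",
             sub("\r", " / ", k), call. = FALSE)
      }
    }
    keep <- !duplicated(key)
    u <- u[keep]; v <- v[keep]; wt <- wt[keep]
  }
  side_a <- sort_lex(unique(u))
  side_b <- sort_lex(unique(v))
  w <- matrix(default_weight, nrow = length(side_a), ncol = length(side_b),
              dimnames = list(side_a, side_b))
  listed <- matrix(FALSE, nrow = length(side_a), ncol = length(side_b),
                   dimnames = list(side_a, side_b))
  idx <- cbind(match(u, side_a), match(v, side_b))
  w[idx] <- wt - threshold
  listed[idx] <- TRUE
  g <- bipartite_graph(side_a, side_b, w, eps = eps)
  attr(g, "listed") <- listed
  g
}

#' @export
print.bcgraph <- function(x, ...) {
  adj <- adjacency(x)
  cat(sprintf(
    "Weighted bipartite graph: %d + %d vertices, %d edges%s\n",
    length(x$a), length(x$b), sum(adj),
    if (any(x$marks != MARK_FREE)) sprintf(" (%d marked pairs)",
                                           sum(x$marks != MARK_FREE))
    else ""))
  invisible(x)
}

# Derived edge indicator: permanent pairs are edges regardless of weight,
# forbidden pairs never are, free pairs iff shifted weight > eps.
#' Adjacency matrix of a bipartite graph
#'
#' @param g a [bipartite_graph()] object.
#' @return logical matrix (side A rows x side B columns), TRUE where the
#'   pair is currently an edge.
#' @export
adjacency <- function(g) {
  g$marks == MARK_PERMANENT | (g$marks == MARK_FREE & g$w > g$eps)
}

#' All vertices of a graph, with sides
#'
#' @param g a [bipartite_graph()] object.
#' @return data.frame with columns `vertex`, `side` ("A"/"B"), in the
#'   deterministic vertex order.
#' @export
vertices_of <- function(g) {
  d <- data.frame(vertex = c(g$a, g$b),
                  side = rep(c("A", "B"), c(length(g$a), length(g$b))),
                  stringsAsFactors = FALSE)
  d[order_lex(d$vertex), , drop = FALSE]
}

#' Current edge list of a graph
#'
#' @param g a [bipartite_graph()] object.
#' @return data.frame with columns `u` (side A), `v` (side B), `weight`
#'   (shifted scale), ordered lexicographically.
#' @export
edges_of <- function(g) {
  adj <- adjacency(g)
  idx <- which(adj, arr.ind = TRUE)
  d <- data.frame(u = g$a[idx[, 1L]], v = g$b[idx[, 2L]],
                  weight = g$w[idx], stringsAsFactors = FALSE)
  d[order(d$u, d$v, method = "radix"), , drop = FALSE]
}

side_of <- function(g, vertex) {
  ifelse(vertex %in% g$a, "A", ifelse(vertex %in% g$b, "B", NA_character_))
}

# Canonical (A, B) orientation of a cross-side pair given as two vertices.
pair_index <- function(g, u, v) {
  i <- match(u, g$a)
  j <- match(v, g$b)
  if (is.na(i) || is.na(j)) {
    i <- match(v, g$a)
    j <- match(u, g$b)
  }
  if (is.na(i) || is.na(j)) {
    stop("not a cross-side pair: ", u, " / ", v, call. = FALSE)
  }
  c(i, j)
}

#' Connected components of a bipartite graph
#'
#' Splits the graph by edge connectivity. Isolated vertices become singleton
#' components. Component subgraphs retain the weights and marks of all their
#' internal cross-side pairs.
#'
#' @param g a [bipartite_graph()] object.
#' @return list of `bcgraph` objects, ordered by their lexicographically
#'   smallest vertex.
#' @export
graph_components <- function(g) {
  memb <- component_membership(g)
  split_by_membership(g, memb)
}

# Integer component id per vertex (named vector over all vertices); ids are
# assigned so that component 1 contains the lexicographically smallest vertex.
component_membership <- function(g) {
  verts <- c(g$a, g$b)
  if (length(verts) == 0L) return(integer(0))
  adj <- adjacency(g)
  idx <- which(adj, arr.ind = TRUE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$a[idx[, 1L]], to = g$b[idx[, 2L]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  memb <- igraph::components(ig)$membership
  memb <- memb[verts]
  # renumber deterministically by smallest member vertex
  ord <- order_lex(verts)
  first_seen <- memb[ord][!duplicated(memb[ord])]
  out <- match(memb, first_seen)
  names(out) <- verts
  out
}

# Subset a graph to a vertex set, preserving weights/marks (and, when
# present, the heuristic's cached culprit scores, which are component-local).
split_by_membership <- function(g, memb) {
  ids <- sort(unique(memb))
  lapply(ids, function(id) subgraph_of(g, names(memb)[memb == id]))
}

subgraph_of <- function(g, vertices) {
  ai <- which(g$a %in% vertices)
  bi <- which(g$b %in% vertices)
  sub <- structure(list(a = g$a[ai], b = g$b[bi],
                        w = g$w[ai, bi, drop = FALSE],
                        marks = g$marks[ai, bi, drop = FALSE],
                        eps = g$eps),
                   class = "bcgraph")
  delta <- attr(g, "delta")
  if (!is.null(delta)) attr(sub, "delta") <- delta[ai, bi, drop = FALSE]
  listed <- attr(g, "listed")
  if (!is.null(listed)) attr(sub, "listed") <- listed[ai, bi, drop = FALSE]
  sub
}

#' Test whether a graph is transitive (a disjoint union of bi-cliques)
#'
#' A bipartite graph is transitive iff it contains no induced path of four
#' vertices (P4), iff every connected component is a complete bipartite
#' graph. The check counts edges per component against the complete count.
#'
#' @param g a [bipartite_graph()] object.
#' @return logical scalar.
#' @export
is_transitive <- function(g) {
  if (length(g$a) == 0L || length(g$b) == 0L) return(TRUE)
  adj <- adjacency(g)
  memb <- component_membership(g)
  ma <- memb[g$a]
  mb <- memb[g$b]
  for (id in unique(memb)) {
    na <- sum(ma == id)
    nb <- sum(mb == id)
    if (na == 0L || nb == 0L) next
    if (sum(adj[ma == id, mb == id, drop = FALSE]) != na * nb) return(FALSE)
  }
  TRUE
}

#' Cost of a set of edge edits
#'
#' Deletions cost the (shifted) weight of the edge; insertions cost minus
#' the weight of the non-edge. Deleting a permanent pair or inserting a
#' forbidden pair costs `Inf`.
#'
#' @param g a [bipartite_graph()] object.
#' @param edits data.frame with columns `u` (side A vertex), `v` (side B
#'   vertex), `op` ("insert"/"delete"); no pair may appear twice.
#' @return numeric total cost (possibly `Inf`).
#' @export
edit_cost <- function(g, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(0)
  i <- match(edits$u, g$a)
  j <- match(edits$v, g$b)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("edit references a same-side or unknown pair", call. = FALSE)
  }
  if (anyDuplicated(cbind(i, j)) > 0L) {
    stop("a pair appears in two edits", call. = FALSE)
  }
  idx <- cbind(i, j)
  w <- g$w[idx]
  mk <- g$marks[idx]
  adj <- adjacency(g)[idx]
  cost <- numeric(nrow(edits))
  del <- edits$op == "delete"
  ins <- edits$op == "insert"
  if (any(!del & !ins)) stop("op must be 'insert' or 'delete'",
                             call. = FALSE)
  if (any(del & !adj) || any(ins & adj)) {
    stop("delete requires an edge; insert requires a non-edge",
         call. = FALSE)
  }
  cost[del] <- ifelse(mk[del] == MARK_PERMANENT, Inf, pmax(0, w[del]))
  cost[ins] <- ifelse(mk[ins] == MARK_FORBIDDEN, Inf, pmax(0, -w[ins]))
  sum(cost)
}

# Apply edits by locking pairs: insertions become permanent edges, deletions
# forbidden non-edges. Weights are untouched, so costs stay auditable.
#' Apply a set of edge edits to a graph
#'
#' @inheritParams edit_cost
#' @return the edited [bipartite_graph()] object.
#' @export
apply_edits <- function(g, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(g)
  idx <- cbind(match(edits$u, g$a), match(edits$v, g$b))
  if (any(is.na(idx))) stop("edit references a same-side or unknown pair",
                            call. = FALSE)
  g$marks[idx[edits$op == "insert", , drop = FALSE]] <- MARK_PERMANENT
  g$marks[idx[edits$op == "delete", , drop = FALSE]] <- MARK_FORBIDDEN
  attr(g, "delta") <- NULL
  g
}

empty_edits <- function() {
  data.frame(op = character(0), u = character(0), v = character(0),
             cost = numeric(0), default_weight = logical(0),
             stringsAsFactors = FALSE)
}
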