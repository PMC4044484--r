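# Solution container shared by all solvers.

#' Bi-cluster editing solutions
#'
#' A solution is a set of edge edits whose application turns the input
#' graph into a disjoint union of bi-cliques, together with its total cost
#' and the resulting vertex clusters.
#'
#' @name bce_solution
#' @section Fields:
#' \describe{
#'   \item{edits}{data.frame with columns `op` ("insert"/"delete"), `u`
#'     (side-A vertex), `v` (side-B vertex), `cost`, `default_weight`
#'     (TRUE for insertions of pairs absent from the input file — the
#'     "putative association" candidates).}
#'   \item{total_cost}{sum of edit costs.}
#'   \item{clusters}{data.frame `cluster`, `vertex`, `side`: the bi-clique
#'     partition after editing.}
#'   \item{optimal}{TRUE only when produced by a completed exact search.}
#'   \item{nodes}{search-tree nodes visited (NA for non-branching solvers).}
#' }
NULL

make_solution <- function(g, edits, optimal, nodes = NA_real_) {
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- empty_edits()
  } else {
    if (!"default_weight" %in% names(edits)) edits$default_weight <- FALSE
    edits <- edits[order(edits$op, edits$u, edits$v, method = "radix"), ,
                   drop = FALSE]
    rownames(edits) <- NULL
  }
  edited <- apply_edits(g, edits)
  memb <- component_membership(edited)
  clusters <- data.frame(cluster = unname(memb),
                         vertex = if (length(memb)) names(memb)
                                  else character(0),
                         side = if (length(memb))
                           ifelse(names(memb) %in% g$a, "A", "B")
                         else character(0),
                         stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster, clusters$vertex,
                             method = "radix"), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(edits = edits, total_cost = sum(edits$cost),
                 clusters = clusters, optimal = optimal, nodes = nodes),
            class = "bce_solution")
}

#' @export
print.bce_solution <- function(x, ...) {
  cat(sprintf("Bi-cluster editing solution: cost %.6g, %d edits (%d del, %d ins), %d clusters%s\n",
              x$total_cost, nrow(x$edits), sum(x$edits$op == "delete"),
              sum(x$edits$op == "insert"),
              length(unique(x$clusters$cluster)),
              if (isTRUE(x$optimal)) " [optimal]" else ""))
  if (nrow(x$edits)) {
    print(utils::head(x$edits, 10L))
    if (nrow(x$edits) > 10L) cat("...\n")
  }
  invisible(x)
}
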