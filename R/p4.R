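# P4 machinery. A P4 (u, v, w, x) is an induced path of four vertices with
# u, w on one side and v, x on the other: uv, vw, wx edges and ux a
# non-edge. A bipartite graph is transitive iff it has no P4. The canonical
# orientation of a path puts the lexicographically smaller endpoint first.

#' Find the canonical first P4 of a graph
#'
#' Scans vertices in the deterministic lexicographic order and returns the
#' lexicographically smallest oriented P4 `(u, v, w, x)`, or `NULL` if the
#' graph is transitive. This is the P4 the branching solver resolves, so the
#' search tree is reproducible.
#'
#' @param g a [bipartite_graph()] object.
#' @return character vector of length 4, or `NULL`.
#' @export
find_p4 <- function(g) {
  na <- length(g$a)
  nb <- length(g$b)
  if (na == 0L || nb == 0L) return(NULL)
  adj <- adjacency(g)
  verts <- sort_lex(c(g$a, g$b))
  for (u in verts) {
    ia <- match(u, g$a)
    if (!is.na(ia)) {
      nu <- adj[ia, ]                       # neighbours of u, over side B
      if (!any(nu)) next
      for (jv in which(nu)) {               # v runs in sorted B order
        nv <- adj[, jv]                     # neighbours of v, over side A
        nv[ia] <- FALSE
        if (!any(nv)) next
        for (iw in which(nv)) {             # w: same side as u
          xs <- which(adj[iw, ] & !nu)      # x adj w, not adj u (v excluded)
          if (length(xs)) {
            return(c(u, g$b[jv], g$a[iw], g$b[xs[1L]]))
          }
        }
      }
    } else {
      ib <- match(u, g$b)
      nu <- adj[, ib]                       # neighbours of u, over side A
      if (!any(nu)) next
      for (jv in which(nu)) {
        nv <- adj[jv, ]
        nv[ib] <- FALSE
        if (!any(nv)) next
        for (iw in which(nv)) {
          xs <- which(adj[, iw] & !nu)
          if (length(xs)) {
            return(c(u, g$a[jv], g$b[iw], g$a[xs[1L]]))
          }
        }
      }
    }
  }
  NULL
}

#' Enumerate all P4s of a graph
#'
#' Returns the full set B(G) of induced four-vertex paths, one row per
#' unordered path in canonical orientation (lexicographically smaller
#' endpoint first). `B(G)` empty is equivalent to [is_transitive()].
#'
#' @param g a [bipartite_graph()] object.
#' @return character matrix with columns `u`, `v`, `w`, `x`; zero rows if
#'   the graph is transitive.
#' @export
enumerate_p4s <- function(g) {
  tab <- p4_table(g)
  m <- tab$quads
  if (nrow(m) == 0L) return(m)
  m[order(m[, 1L], m[, 2L], m[, 3L], m[, 4L], method = "radix"), ,
    drop = FALSE]
}

# Enumerate P4s together with the cost of the cheapest single repair of
# each (the deviation terms): for the three edges the deletion cost, for
# the missing pair the insertion cost; permanent / forbidden pairs are
# unrepairable and enter as +Inf.
p4_table <- function(g) {
  na <- length(g$a)
  nb <- length(g$b)
  quads <- matrix(character(0), ncol = 4L,
                  dimnames = list(NULL, c("u", "v", "w", "x")))
  mins <- numeric(0)
  if (na < 2L || nb < 2L) return(list(quads = quads, mins = mins))
  adj <- adjacency(g)
  dels <- ifelse(g$marks == MARK_PERMANENT, Inf, pmax(0, g$w))
  inss <- ifelse(g$marks == MARK_FORBIDDEN, Inf, pmax(0, -g$w))
  res_q <- list()
  res_m <- list()
  k <- 0L
  for (i1 in seq_len(na - 1L)) {
    for (i2 in seq.int(i1 + 1L, na)) {
      common <- which(adj[i1, ] & adj[i2, ])
      if (!length(common)) next
      only1 <- which(adj[i1, ] & !adj[i2, ])
      only2 <- which(adj[i2, ] & !adj[i1, ])
      # path a_i1 - v - a_i2 - x, x exclusive to a_i2 (and mirrored)
      for (jv in common) {
        for (jx in only2) {
          k <- k + 1L
          res_q[[k]] <- canon_quad(g$a[i1], g$b[jv], g$a[i2], g$b[jx])
          res_m[[k]] <- min(dels[i1, jv], dels[i2, jv], dels[i2, jx],
                            inss[i1, jx])
        }
        for (jx in only1) {
          k <- k + 1L
          res_q[[k]] <- canon_quad(g$a[i2], g$b[jv], g$a[i1], g$b[jx])
          res_m[[k]] <- min(dels[i2, jv], dels[i1, jv], dels[i1, jx],
                            inss[i2, jx])
        }
      }
    }
  }
  if (k == 0L) return(list(quads = quads, mins = mins))
  quads <- do.call(rbind, res_q)
  colnames(quads) <- c("u", "v", "w", "x")
  list(quads = quads, mins = unlist(res_m))
}

canon_quad <- function(u, v, w, x) {
  if (x < u) c(x, w, v, u) else c(u, v, w, x)
}
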