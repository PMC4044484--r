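# Planted-bicluster random graph generator. Emulates the "almost
# transitive" benchmark graphs: vertices are carved into random clusters
# (sizes drawn uniformly from what remains), each vertex lands on side A or
# B by an independent coin flip, and every cross-side pair gets a Gaussian
# weight whose mean depends on whether the pair shares a planted cluster.
# With the default means +/-21 and sd 18, a pair lands on the wrong side of
# the zero threshold ("mistake edge") with probability
# pnorm(-21/18) ~ 0.12.

#' Generator configuration
#'
#' @param n number of vertices.
#' @param mu_intra,mu_inter means of the weight distributions for pairs
#'   sharing / not sharing a planted cluster (defaults +21 / -21).
#' @param sigma_intra,sigma_inter standard deviations (defaults 18).
#' @param side_prob probability a vertex is assigned to side A.
#' @param seed PRNG seed (integer) or NULL to use the current RNG state.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n, mu_intra = 21, mu_inter = -21,
                             sigma_intra = 18, sigma_inter = 18,
                             side_prob = 0.5, seed = NULL) {
  stopifnot(n >= 1, sigma_intra > 0, sigma_inter > 0,
            side_prob > 0, side_prob < 1)
  structure(list(n = as.integer(n), mu_intra = mu_intra,
                 mu_inter = mu_inter, sigma_intra = sigma_intra,
                 sigma_inter = sigma_inter, side_prob = side_prob,
                 seed = seed),
            class = "generator_config")
}

#' Generate a planted-bicluster bipartite graph
#'
#' Cluster sizes are drawn by repeatedly sampling m uniformly from
#' 1..remaining until no vertex is left; sides are independent
#' Bernoulli(`side_prob`) flips. Every cross-side pair receives a weight
#' from N(mu_intra, sigma_intra^2) when both endpoints share a planted
#' cluster and from N(mu_inter, sigma_inter^2) otherwise. The graph is
#' built at threshold 0 (weights are signed by construction). Identical
#' seeds give identical output. Planted clusters that land entirely on one
#' side have no internal edges and surface as singletons once solved; this
#' is a property of the model, not an error.
#'
#' @param config a [generator_config()].
#' @return list with `graph` (a [bipartite_graph()]) and `clusters`
#'   (data.frame `vertex`, `side`, `cluster` — the planted ground truth).
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  # planted cluster ids
  cl <- integer(n)
  left <- n
  next_id <- 1L
  pos <- 1L
  while (left > 0L) {
    m <- sample.int(left, 1L)
    cl[pos:(pos + m - 1L)] <- next_id
    pos <- pos + m
    left <- left - m
    next_id <- next_id + 1L
  }
  width <- max(2L, nchar(as.character(n)))
  verts <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  side <- ifelse(stats::runif(n) < config$side_prob, "A", "B")
  a_idx <- which(side == "A")
  b_idx <- which(side == "B")
  na <- length(a_idx)
  nb <- length(b_idx)
  if (na == 0L || nb == 0L) {
    # degenerate single-sided draw: an edgeless graph
    g <- bipartite_graph(verts[a_idx], verts[b_idx],
                         matrix(numeric(0), nrow = na, ncol = nb))
  } else {
    same <- outer(cl[a_idx], cl[b_idx], "==")
    mu <- ifelse(same, config$mu_intra, config$mu_inter)
    sd_ <- ifelse(same, config$sigma_intra, config$sigma_inter)
    w <- matrix(stats::rnorm(na * nb, mean = mu, sd = sd_),
                nrow = na, ncol = nb)
    g <- bipartite_graph(verts[a_idx], verts[b_idx], w)
  }
  clusters <- data.frame(vertex = verts, side = side, cluster = cl,
                         stringsAsFactors = FALSE)
  list(graph = g, clusters = clusters)
}

#' Analytic mistake-edge probability
#'
#' Probability that a generated pair falls on the wrong side of the zero
#' threshold: an intra-cluster pair with negative weight (missing edge) has
#' probability `pnorm(-mu_intra / sigma_intra)`; an inter-cluster pair with
#' positive weight (spurious edge) has probability
#' `pnorm(mu_inter / sigma_inter)`. At the defaults both equal
#' `pnorm(-21/18)`, about 0.12.
#'
#' @param config a [generator_config()].
#' @return named numeric vector `c(intra = ..., inter = ...)`.
#' @export
mistake_probability <- function(config) {
  c(intra = stats::pnorm(-config$mu_intra / config$sigma_intra),
    inter = stats::pnorm(config$mu_inter / config$sigma_inter))
}

#' Standard deviation achieving a target mistake probability
#'
#' Inverts the mistake-edge relation: `sigma = mu / qnorm(1 - p)` gives a
#' generator whose per-pair mistake probability is exactly `p` for weight
#' mean `mu`.
#'
#' @param p target mistake probability in (0, 0.5).
#' @param mu absolute weight mean (default 21).
#' @return positive numeric.
#' @export
sigma_for_probability <- function(p, mu = 21) {
  stopifnot(p > 0, p < 0.5)
  mu / stats::qnorm(1 - p)
}

#' Solver cost across a sweep of mistake probabilities
#'
#' For each target probability, generates `repeats` planted graphs whose
#' Gaussian spread is calibrated by [sigma_for_probability()], solves each
#' with the requested solvers, and tabulates the total editing cost. Higher
#' mistake probabilities produce noisier graphs, so mean costs are expected
#' to increase along the sweep.
#'
#' @param n vertices per graph.
#' @param probabilities mistake probabilities in (0, 0.5); 0 is allowed as
#'   a degenerate noiseless case.
#' @param repeats graphs per probability.
#' @param seed integer seed; per-graph seeds are derived from it.
#' @param solvers subset of c("heuristic", "exact").
#' @param node_cap node cap per component for the exact solver.
#' @return data.frame with columns `probability`, `rep`, `solver`, `cost`.
#' @export
noise_sweep <- function(n, probabilities, repeats, seed = 1L,
                        solvers = c("heuristic", "exact"),
                        node_cap = Inf) {
  solvers <- match.arg(solvers, several.ok = TRUE)
  out <- list()
  ctr <- 0L
  for (p in probabilities) {
    for (r in seq_len(repeats)) {
      ctr <- ctr + 1L
      gseed <- (as.integer(seed) + 7919L * ctr) %% .Machine$integer.max
      if (p == 0) {
        cfg <- generator_config(n, sigma_intra = 1e-6, sigma_inter = 1e-6,
                                seed = gseed)
      } else {
        s <- sigma_for_probability(p)
        cfg <- generator_config(n, sigma_intra = s, sigma_inter = s,
                                seed = gseed)
      }
      gen <- generate_graph(cfg)
      for (alg in solvers) {
        sol <- solve_graph(gen$graph, algorithm = alg, node_cap = node_cap)
        out[[length(out) + 1L]] <-
          data.frame(probability = p, rep = r, solver = alg,
                     cost = sol$total_cost, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
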