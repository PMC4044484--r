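# Fixture builders shared by the suite. All graphs are built in code; the
# canonical 4-path has a, c on side A and b, d on side B.

path4 <- function(ab = 2, bc = 5, cd = 3, ad = -1) {
  build_graph(data.frame(u = c("a", "c", "c"), v = c("b", "b", "d"),
                         w = c(ab, bc, cd)),
              threshold = 0, default_weight = ad)
}

path5 <- function(w = 2, miss = -1) {
  # a - b - c - d - e with a, c, e on side A
  build_graph(data.frame(u = c("a", "c", "c", "e"),
                         v = c("b", "b", "d", "d"), w = w),
              threshold = 0, default_weight = miss)
}

biclique <- function(na, nb, w = 1) {
  build_graph(expand.grid(u = paste0("a", seq_len(na)),
                          v = paste0("b", seq_len(nb)),
                          w = w, stringsAsFactors = FALSE),
              threshold = 0, default_weight = -1)
}

k22_minus_edge <- function() {
  build_graph(data.frame(u = c("a", "a", "c"), v = c("b", "d", "b"),
                         w = 1),
              threshold = 0, default_weight = -1)
}

# Random Bernoulli bipartite graph with unit weights (edge prob p);
# non-edges get weight -1. Used for brute-force sweeps on <= 8 vertices.
random_unit_graph <- function(na, nb, p, seed) {
  set.seed(seed)
  w <- matrix(ifelse(stats::runif(na * nb) < p, 1, -1), na, nb)
  bipartite_graph(paste0("a", seq_len(na)), paste0("b", seq_len(nb)), w)
}

# Planted-cluster graph at a given mistake probability (paper-style means).
noisy_graph <- function(n, p, seed) {
  s <- sigma_for_probability(p)
  generate_graph(generator_config(n, sigma_intra = s, sigma_inter = s,
                                  seed = seed))
}

# Solve all components exactly and sum costs (callers split so that the
# connectivity precondition of solve_exact holds).
exact_cost_total <- function(g) {
  red <- reduce_graph(g)
  sum(vapply(red$remaining, function(cc) solve_exact(cc)$total_cost,
             numeric(1)))
}

expect_feasible <- function(g, sol) {
  expect_true(is_transitive(apply_edits(g, sol$edits)))
  if (nrow(sol$edits)) {
    expect_true(all(sol$edits$u %in% g$a))
    expect_true(all(sol$edits$v %in% g$b))
    expect_equal(anyDuplicated(sol$edits[, c("u", "v")]), 0L)
  }
  expect_equal(sol$total_cost, sum(sol$edits$cost))
}
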