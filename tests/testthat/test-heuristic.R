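test_that("deviation sums the cheapest repair over all P4s", {
  expect_equal(deviation(path4(ab = 2, bc = 5, cd = 3, ad = -1)), 1)
  expect_equal(deviation(biclique(3, 2)), 0)
  expect_equal(deviation(path5(w = 2, miss = -1)), 2)
})

test_that("deviation vanishes exactly on transitive graphs", {
  for (s in 1:12) {
    p <- c(0.2, 0.5, 0.8)[(s %% 3) + 1]
    g <- random_unit_graph(4, 4, p, seed = 510 + s)
    expect_equal(deviation(g) == 0, is_transitive(g))
  }
})

test_that("transitivity improvement scores deletions by repaired deviation", {
  g <- path4(ab = 2, bc = 5, cd = 3, ad = -1)
  expect_equal(transitivity_improvement(g, "a", "b"), 1 - 0 - 2)
  expect_equal(transitivity_improvement(g, "c", "b"), 1 - 0 - 5)
  g2 <- path4(ab = 10, bc = 1, cd = 10, ad = -10)
  expect_equal(transitivity_improvement(g2, "c", "b"), 0)
  expect_error(transitivity_improvement(g, "a", "d"), "existing edge")
})

test_that("remove_culprit picks the argmax edge with lexicographic ties", {
  rc <- remove_culprit(path4(ab = 2, bc = 5, cd = 3, ad = -1))
  expect_equal(rc$edge, c("a", "b"))
  expect_equal(rc$cost, 2)
  rc2 <- remove_culprit(path4(ab = 10, bc = 1, cd = 10, ad = -10))
  expect_equal(rc2$edge, c("c", "b"))
  # symmetric path: Delta(ab) == Delta(cd); lexicographically smaller wins
  rc3 <- remove_culprit(path4(ab = 2, bc = 5, cd = 2, ad = -1))
  expect_equal(rc3$edge, c("a", "b"))
  # removed edge is forbidden in the returned graph
  expect_equal(unname(rc$graph$marks["a", "b"]), bicledit:::MARK_FORBIDDEN)
  edgeless <- bipartite_graph("a", "b", matrix(-1, 1, 1))
  expect_error(remove_culprit(edgeless), "no deletable edge")
})

test_that("incremental culprit rescoring agrees with full recomputation", {
  for (s in 1:6) {
    gen <- noisy_graph(12, 0.25, seed = 860 + s)
    g <- gen$graph
    for (step in 1:3) {
      if (!any(adjacency(g) & g$marks != bicledit:::MARK_PERMANENT)) break
      rc <- remove_culprit(g)
      g <- rc$graph
      cached <- attr(g, "delta")
      fresh <- bicledit:::culprit_scores(g)
      expect_equal(cached, fresh, tolerance = 1e-9)
    }
  }
})

test_that("transitive closure cost sums required insertions", {
  expect_equal(transitive_closure_cost(path4()), 1)
  expect_equal(transitive_closure_cost(biclique(2, 3)), 0)
  g <- path4()
  g$marks["a", "d"] <- bicledit:::MARK_FORBIDDEN
  expect_equal(transitive_closure_cost(g), Inf)
  gdis <- build_graph(data.frame(u = c("a", "c"), v = c("b", "d"), w = 1))
  expect_error(transitive_closure_cost(gdis), "connected")
})

test_that("the greedy heuristic chooses between closure and deletion correctly", {
  h1 <- edge_del_main(path4(ab = 2, bc = 5, cd = 3, ad = -1))
  expect_equal(h1$total_cost, 1)
  expect_equal(h1$edits$op, "insert")
  h2 <- edge_del_main(path4(ab = 10, bc = 1, cd = 10, ad = -10))
  expect_equal(h2$total_cost, 1)
  expect_equal(h2$edits$op, "delete")
  h3 <- edge_del_main(biclique(2, 2))
  expect_equal(h3$total_cost, 0)
  expect_equal(nrow(h3$edits), 0L)
})

test_that("heuristic output is always feasible, never edits a pair twice, and dominates the optimum", {
  for (i in 1:15) {
    p <- c(0.15, 0.25, 0.35)[(i %% 3) + 1]
    gen <- noisy_graph(10, p, seed = 9400 + i)
    g <- gen$graph
    sol <- solve_graph(g, "heuristic")
    expect_feasible(g, sol)
    # deleted edges are never re-inserted
    key <- paste(sol$edits$u, sol$edits$v)
    expect_equal(anyDuplicated(key), 0L)
    expect_gte(sol$total_cost, exact_cost_total(g) - 1e-6)
  }
})
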