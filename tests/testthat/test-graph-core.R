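test_that("build_graph shifts weights by the threshold and assigns sides by column", {
  g <- build_graph(data.frame(u = "P1", v = "G1", w = 2.0),
                   threshold = 0, default_weight = -1)
  expect_s3_class(g, "bcgraph")
  e <- edges_of(g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 2.0)

  # shifting: stored = input - threshold, edge iff stored > 0
  g2 <- build_graph(data.frame(u = c("x", "x"), v = c("y", "z"),
                               w = c(5, 2)), threshold = 3)
  expect_equal(unname(g2$w["x", "y"]), 2)
  expect_equal(unname(g2$w["x", "z"]), -1)
  expect_equal(edges_of(g2)$v, "y")

  # un-shifting recovers the input weights exactly
  expect_equal(g2$w["x", c("y", "z")] + 3, c(y = 5, z = 2))
})

test_that("p-value weights with the 0.05 threshold give edges iff p < 0.05", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# association table", "s1\tt1\t0.001", "s2\tt1\t0.2",
               "s3\tt1\t0.04999"), tmp)
  rec <- read_edge_tsv(tmp, pvalue = TRUE)
  expect_equal(rec$weight, -log10(c(0.001, 0.2, 0.04999)))
  g <- build_graph(rec, threshold = pvalue_threshold())
  e <- edges_of(g)
  expect_setequal(e$u, c("s1", "s3"))
  expect_false("s2" %in% e$u)
})

test_that("malformed edge records are rejected", {
  expect_error(build_graph(data.frame(u = c("a", "b"), v = c("b", "a"),
                                      w = c(5, 4))),
               "side conflict")
  expect_error(build_graph(rbind(data.frame(u = "a", v = "b", w = 5),
                                 data.frame(u = "a", v = "b", w = 4))),
               "conflicting weights")
  # duplicates with agreeing weights are tolerated
  expect_silent(build_graph(rbind(data.frame(u = "a", v = "b", w = 5),
                                  data.frame(u = "a", v = "b", w = 5))))
  expect_error(build_graph(data.frame(u = "a", v = "a", w = 1)),
               "[Ss]elf-loop")
})

test_that("find_p4 returns the canonical first P4 or NULL", {
  expect_equal(find_p4(path4()), c("a", "b", "c", "d"))
  expect_null(find_p4(biclique(2, 3)))
  # two disjoint edges: no 3-edge path exists
  g <- build_graph(data.frame(u = c("a", "c"), v = c("b", "d"), w = 1))
  expect_null(find_p4(g))
})

test_that("enumerate_p4s counts each unordered path once", {
  expect_equal(nrow(enumerate_p4s(path4())), 1L)
  expect_equal(nrow(enumerate_p4s(k22_minus_edge())), 1L)
  expect_equal(nrow(enumerate_p4s(path5())), 2L)
  expect_equal(nrow(enumerate_p4s(biclique(3, 3))), 0L)
})

test_that("enumerate_p4s agrees with exhaustive 4-subset checking on random graphs", {
  for (s in 1:12) {
    p <- c(0.2, 0.4, 0.6, 0.8)[(s %% 4) + 1]
    g <- random_unit_graph(4, 4, p, seed = 400 + s)
    adj <- adjacency(g)
    # brute force: every (2 rows, 2 cols) quad with exactly 3 of 4 edges
    # contributes two possible paths, but exactly one unordered P4
    cnt <- 0L
    for (i1 in 1:3) for (i2 in (i1 + 1):4) for (j1 in 1:3)
      for (j2 in (j1 + 1):4) {
        ne <- adj[i1, j1] + adj[i1, j2] + adj[i2, j1] + adj[i2, j2]
        if (ne == 3L) cnt <- cnt + 1L
      }
    expect_equal(nrow(enumerate_p4s(g)), cnt)
  }
})

test_that("transitivity, P4-freeness and complete components coincide", {
  for (s in 1:16) {
    p <- c(0.15, 0.35, 0.6, 0.85)[(s %% 4) + 1]
    g <- random_unit_graph(sample(2:4, 1), sample(2:4, 1), p, seed = 70 + s)
    np4 <- nrow(enumerate_p4s(g))
    expect_equal(is_transitive(g), np4 == 0L)
    expect_equal(is.null(find_p4(g)), np4 == 0L)
    comps_complete <- all(vapply(graph_components(g), function(cc) {
      sum(adjacency(cc)) == length(cc$a) * length(cc$b)
    }, logical(1)))
    expect_equal(comps_complete, np4 == 0L)
  }
})

test_that("connected components partition vertices and keep weights", {
  g <- build_graph(data.frame(u = c("a", "c"), v = c("b", "d"), w = c(3, 7)))
  comps <- graph_components(g)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, function(cc) length(cc$a) + length(cc$b),
                      integer(1)), c(2L, 2L))
  expect_equal(unname(comps[[2]]$w["c", "d"]), 7)

  # empty edge set: singletons
  g0 <- bipartite_graph(c("x", "y"), "z",
                        matrix(-1, 2, 1))
  expect_length(graph_components(g0), 3L)
  expect_length(graph_components(path4()), 1L)
})

test_that("edit costs follow the deletion/insertion formula", {
  g <- path4(ab = 5, bc = 2, cd = 3, ad = -3)
  expect_equal(edit_cost(g, data.frame(u = "a", v = "b", op = "delete")), 5)
  expect_equal(edit_cost(g, data.frame(u = "a", v = "d", op = "insert")), 3)
  combo <- data.frame(u = c("c", "a"), v = c("b", "d"),
                      op = c("delete", "insert"))
  expect_equal(edit_cost(g, combo), 5)

  # additive over disjoint edit sets, invariant under reordering
  expect_equal(edit_cost(g, combo[2:1, ]), 5)
  expect_equal(edit_cost(g, combo),
               edit_cost(g, combo[1, ]) + edit_cost(g, combo[2, ]))

  expect_error(edit_cost(g, data.frame(u = "a", v = "c", op = "delete")),
               "same-side|unknown")
  expect_error(edit_cost(g, data.frame(u = c("a", "a"), v = c("b", "b"),
                                       op = c("delete", "delete"))),
               "two edits")
})

test_that("permanent and forbidden marks act as infinite edit costs", {
  g <- path4()
  g$marks["a", "b"] <- bicledit:::MARK_PERMANENT
  g$marks["a", "d"] <- bicledit:::MARK_FORBIDDEN
  expect_equal(edit_cost(g, data.frame(u = "a", v = "b", op = "delete")),
               Inf)
  expect_equal(edit_cost(g, data.frame(u = "a", v = "d", op = "insert")),
               Inf)
  # forbidden pair is not an edge even with positive weight
  g2 <- path4()
  g2$marks["c", "b"] <- bicledit:::MARK_FORBIDDEN
  expect_false("b" %in% edges_of(g2)$v[edges_of(g2)$u == "c"])
  # permanent pair is an edge even with negative weight
  g3 <- path4()
  g3$marks["a", "d"] <- bicledit:::MARK_PERMANENT
  expect_true(any(edges_of(g3)$u == "a" & edges_of(g3)$v == "d"))
})

test_that("is_transitive recognizes unions of bi-cliques", {
  expect_true(is_transitive(biclique(1, 3)))
  expect_false(is_transitive(path4()))
  g <- build_graph(data.frame(u = c("a", "a", "c", "c", "e"),
                              v = c("b", "d", "b", "d", "f"), w = 1))
  expect_true(is_transitive(g))   # K22 + K11
})

test_that("edge-list TSV round trips through write and read", {
  g <- path4(ab = 2.5, bc = 5, cd = 3, ad = -1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(g, tmp)
  back <- read_edge_tsv(tmp)
  expect_equal(back, edges_of(g), ignore_attr = TRUE)
  # raw scale adds the threshold back
  write_edge_tsv(g, tmp, scale = "raw", threshold = 10)
  expect_equal(read_edge_tsv(tmp)$weight, edges_of(g)$weight + 10)
})
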