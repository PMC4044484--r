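test_that("the generator is reproducible and respects its config", {
  cfg <- generator_config(15, seed = 42)
  g1 <- generate_graph(cfg)
  g2 <- generate_graph(cfg)
  expect_identical(g1, g2)

  one <- generate_graph(generator_config(1, seed = 3))
  expect_equal(nrow(one$clusters), 1L)
  expect_equal(length(one$graph$a) + length(one$graph$b), 1L)
  expect_equal(nrow(edges_of(one$graph)), 0L)

  expect_error(generator_config(0), "n >= 1")
  expect_error(generator_config(5, sigma_intra = 0))
})

test_that("analytic mistake probability matches the Gaussian tails", {
  mp <- mistake_probability(generator_config(10))
  expect_equal(unname(mp["intra"]), stats::pnorm(-21 / 18))
  expect_equal(unname(mp["inter"]), stats::pnorm(-21 / 18))
  expect_equal(unname(mp["intra"]), 0.1217, tolerance = 1e-3)

  mp0 <- mistake_probability(generator_config(10, mu_intra = 0,
                                              mu_inter = 0))
  expect_equal(unname(mp0), c(0.5, 0.5))

  mp_small <- mistake_probability(generator_config(10, sigma_intra = 1e-9,
                                                   sigma_inter = 1e-9))
  expect_equal(unname(mp_small), c(0, 0), tolerance = 1e-12)
})

test_that("sigma_for_probability inverts the mistake-edge relation", {
  expect_equal(sigma_for_probability(stats::pnorm(-21 / 18)), 18)
  p <- 0.123
  mp <- mistake_probability(
    generator_config(5, sigma_intra = sigma_for_probability(p),
                     sigma_inter = sigma_for_probability(p)))
  expect_equal(unname(mp["intra"]), p, tolerance = 1e-12)
})

test_that("empirical mistake frequency converges to the analytic value", {
  # ~10^4 cross pairs; binomial 4-sigma band around pnorm(-21/18)
  gen <- generate_graph(generator_config(200, seed = 77))
  g <- gen$graph
  cl <- gen$clusters
  same <- outer(cl$cluster[match(g$a, cl$vertex)],
                cl$cluster[match(g$b, cl$vertex)], "==")
  mistakes <- (same & g$w < 0) | (!same & g$w > 0)
  n_pairs <- length(mistakes)
  expect_gte(n_pairs, 9000)
  p <- stats::pnorm(-21 / 18)
  expect_lt(abs(mean(mistakes) - p), 4 * sqrt(p * (1 - p) / n_pairs))
})

test_that("near-zero noise yields zero-cost instances that keep planted clusters", {
  gen <- generate_graph(generator_config(20, sigma_intra = 1e-6,
                                         sigma_inter = 1e-6, seed = 5))
  g <- gen$graph
  expect_true(is_transitive(g))
  expect_equal(solve_graph(g, "heuristic")$total_cost, 0)
  sol <- solve_graph(g, "exact")
  expect_equal(sol$total_cost, 0)
  # every cross-side-connected planted cluster is one output cluster
  got <- lapply(split(sol$clusters$vertex, sol$clusters$cluster), sort)
  for (cid in unique(gen$clusters$cluster)) {
    verts <- sort(gen$clusters$vertex[gen$clusters$cluster == cid])
    sides <- gen$clusters$side[gen$clusters$cluster == cid]
    if (length(unique(sides)) < 2L) next   # one-sided: edgeless singletons
    expect_true(any(vapply(got, identical, logical(1), verts)))
  }
})

test_that("noise_sweep tabulates both solvers and handles the degenerate p = 0", {
  tab <- noise_sweep(8, c(0, 0.2), repeats = 2, seed = 9,
                     solvers = c("heuristic", "exact"))
  expect_setequal(names(tab), c("probability", "rep", "solver", "cost"))
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$cost[tab$probability == 0] == 0))
  expect_true(all(tab$cost[tab$solver == "heuristic"] >=
                    tab$cost[tab$solver == "exact"] - 1e-6))
})
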