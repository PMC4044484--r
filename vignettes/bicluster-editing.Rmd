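---
title: "Weighted bi-cluster editing: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted bi-cluster editing: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicledit)
```

## The model

Two-mode biomedical data — SNPs against traits, genes against conditions,
genes against species — are modeled as a weighted bipartite graph
$G = (V, E, s)$ with a symmetric similarity $s : V^2 \to \mathbb{R}$
defined on cross-side pairs and an edge set
$E = \{uv : s(uv) > t\}$ for a user threshold $t$. Group structure
corresponds to *bi-cliques* (complete bipartite subgraphs); a bipartite
graph whose components are all bi-cliques is called *transitive*, and a
graph is transitive exactly when it contains no induced path on four
vertices (a *P4*: three edges $uv, vw, wx$ plus the missing closing pair
$ux$).

Weighted bi-cluster editing asks for a transitive $G'$ minimizing

$$\mathrm{cost}(G \to G') \;=\; s(E \setminus E') \;-\; s(E' \setminus E),$$

so deleting an edge costs its similarity and inserting a missing pair
costs the negative of its (sub-threshold) similarity. The problem is
NP-hard, but fixed-parameter tractable in the total modification cost
$k$.

This is **not** submatrix biclustering of expression data: clusters here
are vertex-disjoint, and the output is a partition of both vertex sets
simultaneously, not a set of overlapping submatrices.

### The threshold shift

Internally every weight is stored *shifted*: $\tilde s(uv) = s(uv) - t$,
so edge presence is simply $\tilde s > 0$ and the deletion/insertion
costs are $|\tilde s|$ on both sides of the threshold. The cost scale of
the problem statement leaves open whether raw or shifted weights enter
the objective; the shifted convention is used because it makes costs
continuous at the threshold (a pair scoring just above $t$ is almost
free to delete, one just below almost free to insert). Pairs absent from
an input file receive a user-set `default_weight` on the shifted scale
(default $-1$): association tables are sparse, and an unlisted pair is
treated as mildly dissimilar rather than unknown. Insertions of such
pairs are flagged in the output (`default_weight = TRUE`) so that
predicted "putative associations" can be audited. Weights exactly at the
threshold (shifted weight within $\varepsilon = 10^{-9}$ of zero) are
non-edges, matching the strict inequality; all floating-point cost
comparisons use the same $\varepsilon$.

For *p*-value association tables (`pvalue = TRUE`) the similarity is
$-\log_{10} p$ and the default threshold $-\log_{10} 0.05 \approx 1.301$,
so an edge is exactly a nominally significant association.

## Data reduction

Both solvers operate per connected component (an optimal solution never
joins separate components — merging two components is always at least as
expensive as leaving them apart, which the test-suite re-verifies against
the exhaustive oracle). `reduce_graph()` splits the instance and emits
every component that is already a bi-clique — checked by comparing its
edge count with $|A|\cdot|B|$, linear time, no P4 enumeration — as a
zero-cost partial solution. Reduction never changes the optimum and is
idempotent.

## The exact fixed-parameter solver

`solve_exact()` resolves P4s recursively. At each node the *canonical*
P4 is located — the lexicographically smallest quadruple $(u, v, w, x)$
under the C-locale vertex order, which makes search traces reproducible —
and four branches are explored in a fixed order: insert $ux$, delete
$uv$, delete $wv$, delete $wx$. An inserted pair is marked *permanent*
(undeletable, weight effectively $+\infty$), a deleted pair *forbidden*
(uninsertable, $-\infty$); marks travel with each branch, so no pair is
ever edited twice on a root-to-leaf path and the tree is finite. A branch
whose edit cost exceeds the remaining budget is pruned ($k' < 0$). With
all $|\tilde s| > 1$ the tree has at most $4^{\lceil k\rceil}$ nodes.

**Finding the minimum $k$.** The problem statement only defines search
within a given budget; how the minimal budget is located is left open.
Iterative deepening over $k$ suits integer costs but not real-valued
ones, so the solver runs a single branch-and-bound pass instead: the
greedy heuristic provides the incumbent upper bound, every strict
improvement tightens it, and when the tree is exhausted the incumbent is
provably optimal (`optimal = TRUE`). `branch_search(g, k)` exposes the
plain budgeted search: the cheapest solution within $k$, or `NULL` when
every branch prunes. Equal-cost optima are possible; the solver returns
the first one found in branch order (a single solution, deterministically
chosen — enumeration of *all* optima is left as a documented extension
point).

The recursion itself is compiled (Rcpp); it was ported from, and verified
node-for-node against, an R reference implementation. On components
exceeding `exact_size_cap` vertices (default 40, where branching becomes
impractical) the `auto` mode keeps the heuristic answer; explicit
`node_cap`/`time_limit` arguments abort the search cleanly, returning the
best incumbent flagged non-optimal with a warning.

## The greedy edge-deletion heuristic

Deletions are the hard part of the problem: they decide how many
bi-cliques emerge, whereas once components are fixed the insertions are
forced (complete each component). The heuristic therefore places
deletions first. Define the *deviation from transitivity*

$$D(G) = \sum_{uvwx \in \mathrm{P4}(G)} \min\{|\tilde s(uv)|,
|\tilde s(vw)|, |\tilde s(wx)|, |\tilde s(xu)|\},$$

the total cost of the cheapest single repair of every P4 ($D(G) = 0$ iff
$G$ is transitive), and score each edge by the *transitivity improvement*

$$\Delta_{uv}(G) = D(G) - D(G') - \tilde s(uv),$$

where $G'$ is $G$ with $uv$ removed and marked forbidden. Only P4s whose
vertex set contains both $u$ and $v$ change between $G$ and $G'$, so each
score is computed from $O(|V|^2)$ quads; after a deletion only affected
edges are rescored (edges sharing an endpoint with the deleted pair are
recomputed, every other edge shares exactly one quad with it and is
adjusted by that quad's contribution change). The cached incremental
scores are asserted equal to full recomputation in the test-suite.

A forbidden pair contributes $+\infty$ insertion cost: a P4 whose missing
pair is forbidden keeps the minimum over its three finite edge weights,
and P4s that used the pair as an edge cease to exist. (The alternative
reading — a literal $-\infty$ operand inside $\min |\cdot|$ — would make
every such P4 free to repair, which contradicts the pair being
unrepairable.)

`edge_del_main()` realizes "delete until it stops paying" as an exact
comparison at every recursion level: compute the closure cost of the
component (all missing insertions), tentatively delete the culprit edge
$\arg\max_{uv} \Delta_{uv}$ (ties broken lexicographically), recurse on
the resulting components, and keep the cheaper of the two totals (ties
favor closure — fewer structural changes). Each edge is deleted at most
once across all levels and never re-inserted, giving the
$O(|E|(|E|+|V|^2) + |V|^3)$ overall bound. Whether the original
formulation compared closure against deletion once per component or at
every level is not specified; the per-level comparison is the faithful
reading of "until further deletions do not improve the solution" and is
never worse. The result is always feasible, and bounds the optimum from
above (asserted against the exact solver and the oracle throughout the
tests).

## The brute-force oracle

`brute_force_optimal()` enumerates every partition of the vertex set via
restricted-growth strings and charges each partition the deletions
between blocks plus the insertions missing within blocks. It refuses
instances above 10 vertices (Bell-number blow-up) and contains no pruning
on purpose: it is the obviously-correct ground truth that the branching
solver is tested against. Blocks consisting of one side only are legal
(they are edgeless and cost nothing) and are reported as singletons.

## The synthetic generator

`generate_graph()` emulates the benchmark model: cluster sizes are drawn
sequentially, $m \sim \mathrm{Uniform}\{1, \dots, \text{remaining}\}$,
until no vertex remains; every cross-side pair gets
$N(\mu_\text{intra}, \sigma^2)$ weight if its endpoints share a planted
cluster and $N(\mu_\text{inter}, \sigma^2)$ otherwise, with defaults
$\mu_\text{intra} = 21$, $\mu_\text{inter} = -21$, $\sigma = 18$. A
*mistake pair* — an intra pair sampled negative or an inter pair sampled
positive — occurs with probability $\Phi(-21/18) \approx 0.122$
(`mistake_probability()`), and `sigma_for_probability()` inverts the
relation, $\sigma = \mu / \Phi^{-1}(1 - p)$, to calibrate graphs to a
target mistake rate for noise sweeps.

Two aspects of the model are under-specified and were fixed once:

* **Side assignment.** Nothing states how planted clusters span the two
  sides; each vertex is assigned to side A independently with probability
  `side_prob` (default 0.5). Clusters landing entirely on one side have
  no internal edges and surface as singletons — a documented property of
  the model, not an error.
* **Cluster-size law.** "$m \in [1, n]$" is read as uniform over the
  vertices still unassigned, rather than uniform over $[1, n]$ with
  rejection; with rejection, large clusters would be over-represented
  late in the process.

Because of these freedoms (and because published cost tables average few
repeats of the same under-specified process), *absolute* editing costs of
generated graphs are not reproducible benchmarks; ratio, dominance and
trend properties are, and those are what the acceptance checks assert.

What the generator does **not** emulate about real association data:
sparsity (real tables list only tested pairs; the generator scores every
pair), heavy-tailed and correlated scores, hub vertices, and cluster
overlap. Passing tests on generated graphs therefore demonstrate solver
correctness and calibration of the noise model — not that any particular
biological data set will produce meaningful clusters at a given
threshold.

## Problem sizes and test design

The exhaustive oracle bounds its instances at 10 vertices, so
oracle-equivalence and reduction-soundness checks run on graphs of 4–8
vertices (100+ random graphs across mistake probabilities 0.1–0.4).
Heuristic quality is measured on planted graphs of 10 and 20 vertices at
the default generator parameters, 20 seeds each: the mean
heuristic/exact cost ratio stays below 1.10 (typical measured values
1.01–1.05). The noise sweep uses 20-vertex graphs at
$p \in \{0.1, 0.2, 0.3, 0.4\}$ with 5 repeats; low-noise recovery uses
$p = 0.02$ and 24–30 vertices over 10 seeds. These sizes keep the whole
suite within a couple of minutes on one CPU while exercising every code
path; the solvers themselves handle larger components (the practical
exact limit is around 40 vertices, hence the default `exact_size_cap`).

**Recovery is checked per component.** At $p = 0.02$ a planted cluster
occasionally attracts a foreign vertex through two or more mistake edges,
and the *true optimum* then merges them — the exact solver is right and
the plant is wrong. The recovery check therefore asserts: every
connected component whose vertex set coincides with a single connected
planted cluster is returned intact as one bi-clique. Components
contaminated by cross-cluster mistake edges are judged by optimality
(exact = oracle), not by the plant.

## Numerical choices, degenerate inputs, limitations

* Comparison tolerance $\varepsilon = 10^{-9}$ throughout; a branch is
  pruned when its cost exceeds the remaining budget by more than
  $\varepsilon$, and "strictly better" means better by more than
  $\varepsilon$.
* All vertex and pair orderings are C-locale (radix) string order, so
  culprit tie-breaks, P4 canonicalization and output files are
  platform-independent.
* Self-loops and vertices appearing on both sides are rejected at parse
  time; duplicate records are tolerated only when their weights agree.
* Edgeless vertices are singleton components, solved by reduction at zero
  cost. Empty inputs yield empty zero-cost solutions.
* Permanent/forbidden marks in *input* graphs are honored (infinite
  deletion/insertion costs) but are primarily solver-internal state.
* The heuristic has no lookahead beyond one tentative deletion per level
  and no randomized restarts; on adversarial weightings it can exceed the
  optimum by more than the ~5% seen on planted graphs (the guarantee is
  feasibility and an upper bound, not an approximation factor).
* Single-process execution; components are independent, so coarse
  parallelism is trivial for the caller but deliberately out of scope.

## A worked call

```{r example}
path <- system.file("extdata", "associations.tsv", package = "bicledit")
sol <- solve_file(path, algorithm = "exact", quiet = TRUE)
sol
sol$clusters
```

The flagged insertion is the putative association predicted by the
group-to-group structure; the run report
(`attr(sol, "report")`) records per-component sizes, the algorithm used,
cost, optimality and search-tree nodes.
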