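# bicledit — weighted bi-cluster editing of bipartite similarity graphs

Many biomedical data sets relate two kinds of objects at once: SNPs and
traits in genome-wide association studies, genes and conditions in
expression screens, genes and species in comparative genomics. Such data
form a weighted **bipartite graph**: an edge connects a side-A object to a
side-B object whenever their similarity (or association score) clears a
threshold. Group structure in these data corresponds to **bi-cliques** —
complete bipartite subgraphs in which every A-object is linked to every
B-object. Measurement noise hides this structure: real similarity graphs
contain spurious edges and missing ones.

**Weighted bi-cluster editing** recovers the hidden group structure by
modifying the graph as little as possible. Given *G* = (*V*, *E*, *s*)
with a symmetric similarity *s*: *V*² → ℝ and edge set
*E* = {*uv* : *s*(*uv*) > *t*}, find a disjoint union of bi-cliques *G′*
minimizing

    cost(G → G′) = s(E \ E′) − s(E′ \ E)

i.e. deleted edges pay their weight and inserted non-edges pay the
(negative) weight of the missing pair. A bipartite graph is a disjoint
union of bi-cliques exactly when it contains no **P4** — no induced path
on four vertices. The problem is NP-hard; this package implements

* an **exact fixed-parameter solver**: recursive 4-way branching on P4s
  (insert the closing pair, or delete one of the three path edges), with
  pairs locked *permanent*/*forbidden* along each branch, pruned by the
  remaining modification budget *k* and an incumbent upper bound
  (`solve_exact()`, `branch_search()`; compiled core, O(4ᵏ) worst case);
* a polynomial **greedy edge-deletion heuristic**: deletions are scored by
  the *transitivity improvement* Δ(uv) = D(G) − D(G′) − s(uv), where the
  *deviation from transitivity* D(G) sums, over all P4s, the cheapest
  single repair; the best-scoring edge is deleted until further deletions
  no longer beat closing each component into a bi-clique
  (`edge_del_main()`, `deviation()`, `remove_culprit()`);
* a **planted-bicluster generator** with two-Gaussian edge weights
  (intra-cluster N(21, 18²), inter-cluster N(−21, 18²)), giving
  "almost transitive" benchmark graphs with an analytic mistake-edge
  probability Φ(−21/18) ≈ 0.12 (`generate_graph()`,
  `mistake_probability()`, `noise_sweep()`);
* a **brute-force oracle** enumerating all vertex partitions for small
  instances, the ground truth of the test-suite (`brute_force_optimal()`);
* TSV readers/writers (including −log₁₀ *p*-value association tables with
  the 0.05 ↦ 1.301 threshold), per-component dispatch with data reduction,
  and a command-line front end.

## Worked example

`inst/extdata/associations.tsv` holds a small synthetic phenotype–SNP
score table: phenotypes P1, P2 share SNPs G1, G2 except that the pair
P2–G2 was never scored significant, and P3 (anchored to its own SNP G3)
carries one weak spurious link to G2.

```r
library(bicledit)
path <- system.file("extdata", "associations.tsv", package = "bicledit")
sol <- solve_file(path, algorithm = "exact", quiet = TRUE)
print(sol)
#> Bi-cluster editing solution: cost 2, 2 edits (1 del, 1 ins), 2 clusters [optimal]
#>       op  u  v cost default_weight
#> 1 delete P3 G2    1          FALSE
#> 2 insert P2 G2    1           TRUE
print(sol$clusters)
#>   cluster vertex side
#> 1       1     G1    B
#> 2       1     G2    B
#> 3       1     P1    A
#> 4       1     P2    A
#> 5       2     G3    B
#> 6       2     P3    A
```

The optimal editing (total cost 2) deletes the spurious P3–G2 association
and inserts P2–G2. The inserted pair is flagged `default_weight = TRUE`
because it was absent from the input — it is a *putative association*
predicted by the group-to-group structure, the quantity of interest when
this model is applied to association data. The result is two bi-cliques:
{P1, P2} × {G1, G2} and {P3} × {G3}.

The same run from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bicledit.R", package = "bicledit"))')" \
    solve inst/extdata/associations.tsv --algorithm exact --out-prefix run
# total cost  2
# edits       2
# clusters    2
# optimal     TRUE
```

which writes `run_edits.tsv`, `run_clusters.tsv` and `run_report.json`;
`... check` verifies them against the input.

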