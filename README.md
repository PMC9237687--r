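# pangraphr

Tools for interrogating and transforming **pangenome variation graphs**
in R.

A variation graph `V = (N, E, P)` stores a mutual alignment of many
genomes: nodes `N` carry DNA sequences (each with an implicit reverse
complement), edges `E` connect ordered pairs of node strands, and paths
`P` embed whole genomes, haplotypes or contigs as walks over node
strands. Since every input sequence is a path, path coordinates form a
universal coordinate system: any embedded genome can act as the
reference for annotation, liftover or copy-number analysis, and the
graph stays invisible to downstream tools that expect plain sequences
and BED/PAF intervals.

`pangraphr` implements a node-centric in-memory model of this graph —
per-node records holding the sequence, delta-encoded adjacency
(`delta = id_from − id_to`) and doubly-linked path steps — and the
standard toolkit over it:

* **I/O** — lossless GFAv1 reading/writing with canonical emission,
  PanSN (`sample#haplotype#contig`) name parsing, a native serialized
  format (`read_gfa`, `write_gfa`, `save_native`, `load_native`).
* **Editing** — `vg_chop` / `vg_unchop` (node splitting and unitig
  merging, path sequences conserved exactly), `vg_extract` on path
  ranges with context hops, `vg_explode` / `vg_squeeze`, `vg_prune`,
  `vg_apply_order`.
* **Metrics** — `vg_stats` (nodes, edges, paths, components, length, GC;
  YAML out), node depth/degree as scalars and per-nucleotide BED tracks,
  `vg_flatten` (FASTA + BED), `paths_fasta`, `pangenome_matrix`.
* **Ordering & layout** — `topological_order`, and the path-guided
  stochastic gradient descent **PG-SGD** in 1D (`pg_sgd_1d`) and 2D
  (`pg_sgd_2d`), which minimizes `Σ w (d − dist)²` with `w = d⁻²` over
  step pairs sampled along the embedded paths, `d` their nucleotide
  distance; `layout_stress` is the matching diagnostic.
* **Liftover & untangling** — `translate_position` resolves repeat
  visits by **path-jaccard context mapping** (the multiset of node ids
  within a bp radius along the path, compared by multiset jaccard);
  `vg_untangle` segments query paths against a reference at loop-back
  boundaries and emits PAF rows; `self_coverage` turns them into
  per-base copy number.
* **Visualization** — `render_1d` (binned paths x pangenome-position
  raster with name / position / strand / depth modalities; the depth
  palette is white/gray/red/yellow for 0/1/2/≥3), `draw_svg` for 2D
  layouts, PPM/PNG writers.
* **Synthetic graphs** — seeded generators with planted truth
  (`fixture_linear`, `fixture_bubble`, `fixture_cnv`, `fixture_repeat`,
  `fixture_random`); no external data is needed anywhere.

A thin command-line front end ships in `exec/pangraph`
(`pangraph build|view|stats|sort|layout|viz|untangle|... `).

## Worked example

The running toy graph is a single bubble — four nodes with two embedded
haplotypes `x = 1+,2+,4+` and `y = 1+,3+,4+`:

```r
library(pangraphr)
g <- vg_example_graph()
g
#> <variation graph: 4 nodes, 4 edges, 2 paths, 8 bp>
vg_path_sequence(g, "x")
#> [1] "ACGTATT"
vg_stats(g)
#> n_nodes: 4
#> n_edges: 4
#> n_paths: 2
#> n_components: 1
#> length_bp: 8
#> gc_fraction: 0.375
depth_over_path(g, "x")
#>   name start end value
#> 1    x     0   4     2
#> 2    x     4   5     1
#> 3    x     5   7     2
```

The depth track reads: bases 0–4 of `x` sit on node 1, which both
haplotypes cross (depth 2); base 4 sits on the `x`-private bubble arm
(depth 1); bases 5–7 are shared again.

Untangling a copy-number fixture (a query that traverses a 4 bp
reference segment twice) recovers the planted copy number:

```r
fx <- fixture_cnv(copies = 2, seg_nodes = 4, seed = 1)
u <- vg_untangle(fx$graph, "q", "r", merge_dist = 1, radius = 2)
u[, c("query_start", "query_end", "strand", "target_start", "target_end")]
#>   query_start query_end strand target_start target_end
#> 1           0         6      +            0          6
#> 2           6        10      +            2          6
#> 3          10        14      +            6         10
self_coverage(u, "r")
#>   name start end value
#> 1    r     0   2     1
#> 2    r     2   6     2
#> 3    r     6  10     1
```

The middle row is the second pass over the duplicated segment
(reference interval `[2,6)`), so its copy number reads 2 there and 1 in
the flanks.

Sorting a 50-node chain whose ids were randomly permuted:

```r
f <- fixture_linear(50, 10, seed = 42)
lay <- pg_sgd_1d(f$graph, seed = 1)
lay
#> <1D PG-SGD layout of 50 nodes; stress 2.234e-18 (from 94.83)>
sorted <- vg_apply_order(f$graph, layout_order(lay))
ed <- vg_edges(sorted)
mean(abs(ed$from_id - ed$to_id) == 1)   # edges between consecutive ids
#> [1] 1
```

Stress drops from 94.8 to ~0 and every edge of the re-ordered graph
connects consecutive ids — the layout has fully recovered the chain.

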