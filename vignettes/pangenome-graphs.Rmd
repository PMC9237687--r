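---
title: "Models and methods: interrogating pangenome variation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: interrogating pangenome variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangraphr)
```

## The variation graph model

A pangenome variation graph is a bidirected sequence graph
$V = (N, E, P)$: nodes $n_1 \dots n_{|N|}$ carry genomic sequences (each
node has an implicit reverse complement, so a *node strand*, or handle, is
one of its two orientations); edges are ordered pairs of node strands
$e_i = (s_a, s_b)$, where $(s_a, s_b)$ and
$(\overline{s_b}, \overline{s_a})$ denote the same edge; and paths
$p_i = s_1 \dots s_{|p_i|}$ are walks over node strands that embed whole
genomes, haplotypes or contigs in the graph. Because every embedded
sequence is a path, path coordinates give a universal, graph-independent
coordinate system: any genome in the graph can serve as the reference for
annotation, liftover, or copy-number analysis.

`pangraphr` keeps the graph node-centric. Each node record holds its
sequence, its incident edges, and the vector of path steps crossing it;
steps form doubly-linked lists whose `prev`/`next` pointers are a
*delta-encoded* node id (`delta = id_from - id_to`) plus a rank into the
neighbor's step vector. Only path heads/tails and the name-to-id map are
global. Two properties of real pangenome graphs motivate this layout:
they are sparse, and they can be sorted so that most edges connect nearby
ids — which makes the deltas small. We store the signed deltas directly;
bit-packing them into succinct vectors is an internal representation
concern that desk-scale graphs do not need, so the storage contract is
checked as *counts* (two integers per edge record, at most eight per
step), not bits.

Every mutation touches at most two node records. In a concurrent
implementation, per-node exclusive access would be acquired in ascending
id order and released in descending order to avoid deadlocks; this
package's implementation is serial and deterministic, which satisfies
that contract vacuously.

Decisions where the model left room:

* **Empty paths** (metadata with zero steps) are permitted and exempt
  from the one-start/one-end invariant.
* **Step ranks** are positional indices into a node's step vector;
  structural rewrites rebuild the affected vectors and repair the
  neighbors' ranks.
* **Node ids need not be dense**; auto-assignment uses `max_id + 1`.
* **`N` bases** are legal sequence, counted in graph length but never as
  G/C.

## GFA dialect and the native format

Only GFAv1 `H`/`S`/`L`/`P` records are accepted. Pangenome graphs are
blunt-ended, so link overlaps other than `*`/`0M` are rejected loudly
rather than silently truncated; GFAv2 record types and rGFA `SN` tags
raise errors. `W` lines are out of scope. Segment names that are all
positive integers become node ids directly; otherwise every name is
mapped to a fresh id in first-seen order and kept in a translation table
that emission restores, so conversion is lossless either way. Emission
uses a fixed canonical order (header; `S` by ascending id; `L` by
canonical endpoints; `P` in creation order), which makes
`write(parse(write(g)))` byte-identical to `write(g)` and lets the test
suite compare record multisets exactly. PanSN names
(`sample#haplotype#contig`) are parsed strictly: anything without exactly
two delimiters falls back to "bare contig" rather than a guess, since the
convention allows `#` inside contig names.

The native serialized format is a magic string and a version byte ahead
of a serialized snapshot of the node and path tables (translation table
included). Truncation or a bad magic/version is a format error; no
partial graph is ever returned.

## Editing

`vg_chop(k)` splits long nodes greedily left-to-right into `<= k` bp
pieces with fresh ascending ids, reattaches edges to the terminal pieces,
and replaces each step through a split node by the ordered piece steps
(reversed for reverse steps). `vg_unchop()` merges unitig chains: a pair
`a -> b` merges only when `a`'s strand has `b` as unique successor, `b`
has `a` as unique predecessor, no other edge meets the junction, and
*every* path crosses the junction in one consistent pass — a conservative
rule that can never create chimeric sequence. Merged nodes take the
smallest id of their chain. Both operations conserve every path sequence
exactly, and `unchop(chop(k))` reaches the same normal form for any `k`;
the tests assert this for `k` in {1, 2, 3, 5} and on randomized graphs.

`vg_extract()` selects nodes by the *steps* of the requested path ranges
(not by coordinate projection), expands by breadth-first hops, and
induces all edges among selected nodes — tying extraction to the path
coordinate space. Surviving runs of other paths become subpaths named
`name:start-end` in 0-based half-open coordinates (BED convention); a run
covering the whole path keeps its original name, so extraction over a
full range or pruning with slack thresholds is the identity.
`vg_prune()` drops whole nodes over a depth or degree threshold — one
deterministic mode rather than the many pruning variants a full toolkit
grows. `vg_explode()`/`vg_squeeze()` partition and unify components, with
id shifting and `#i`-suffixed renaming of colliding path names.

## Metrics

*Node depth* is the number of path steps on a node (all paths, both
orientations); *degree* counts distinct incident edges, a self-loop once.
`depth_over_path()`/`degree_over_path()` report the per-nucleotide value
under each base of a path as run-length-merged BED intervals that tile
`[0, path length)` exactly. The GC fraction in `vg_stats()` counts each
node's sequence once — it is a property of the graph sequence, not
weighted by how many paths cross a node — with `N` in the denominator
only; a single `length_bp` field reports the graph length. The YAML
emission uses the keys `n_nodes`, `n_edges`, `n_paths`, `n_components`,
`length_bp`, `gc_fraction`.

## Node ordering and layout

`topological_order()` is a Kahn-style sort in handle space: a strand is
ready when all edges on its incoming side come from placed nodes; seeds
prefer edge-free strands at the lowest id, and when only cycles remain
the lowest unplaced id is forced (back edges permitted).

The path-guided stochastic gradient descent (PG-SGD) learns node
positions that match nucleotide distances along the embedded paths. It
minimizes
$$\sum_{\text{terms}} w \,(d - \mathrm{dist})^2, \qquad w = d^{-2},$$
where a term is a pair of steps of one path, $d$ their bp distance, and
$\mathrm{dist}$ the current layout distance. Terms are sampled by
choosing a step uniformly and a second step of the same path at a
Zipf-distributed rank offset (exponent 0.99, maximum offset the path's
step count): short-range terms refine local order, the long tail carries
the global untangling signal. Per term both endpoints move by the
correction $(\mathrm{dist} - d)/2$ scaled by
$\mu = \min(1, \eta_t w)$; $\eta_t$ decays geometrically from
`eta_max` (default: the squared maximum sampled distance, which
saturates early moves at $\mu = 1$) to `eps` (default 0.01) over 30
iterations, stopping early if the largest displacement of a round falls
below `eps`.

Choices worth flagging:

* **1D places node midpoints** and measures distances
  midpoint-to-midpoint. Placing node *ends* instead is equally defensible;
  midpoints keep the 1D state one number per node.
* **Terms per iteration** default to 20 x the total step count. At lower
  sampling densities a few percent of runs on 50-node permuted chains
  ended in a folded local minimum (the chain doubled back on itself); at
  20x we observed no folds in 120 runs, and the cost is well under a
  second at these sizes.
* **2D** lays out the two endpoints of each node; a zero rank offset
  pairs a step's own endpoints at the node's length, keeping nodes
  extended. Initialization is the 1D prefix-sum offsets in current id
  order plus seeded uniform noise in y — nothing in the objective pulls
  two untied branches together, so the noise also keeps parallel bubble
  arms from starting superimposed.
* The serial implementation is exactly reproducible under a seed.

`layout_stress()` reports a Monte-Carlo estimate of the same objective
(mean per sampled term), which the tests use to check that optimization
always reduces stress from the initial placement.

## Liftover, untangling, copy number

`translate_position()` lifts a query path position onto a target path.
The base's node may be visited several times by the target (a collapsed
repeat); the winning visit is the one whose *context* — the multiset of
node ids whose step spans intersect a closed window of `radius` bp around
the position, walked along that single path — maximizes the multiset
jaccard $|a \cap b| / |a \cup b|$ (elementwise min over max) with the
query's context. Ties break to the smallest target offset; a target that
never visits the node is a no-hit result, not an error. The default
radius is 10 kbp, the scale at which repeat copies typically differ in
their flanks; context is deliberately single-path (multi-path expansion
is a possible variant, not the default).

`vg_untangle()` maps every query base to an implied reference coordinate
and strand via this translation (choosing the best-scoring reference
path per base) and cuts the query into segments at four kinds of
boundary: the best reference path changes, the strand flips, the implied
coordinate jumps by more than `merge_dist` (default 10 kbp, matching the
context radius so segments stay stable), or the *loop-back state*
changes. The last rule operationalizes "breaking segments where paths
loop back on themselves": a base is *advancing* when its implied
coordinate moves past the farthest reference point reached so far (per
reference and strand) and *looping* while it re-traverses
already-covered reference; a copy of a duplicated segment is exactly a
maximal looping run, so both its entry and its exit become segment
boundaries. Each segment yields one PAF-style row (target interval = the
span of its implied coordinates, jaccard = mean per-base winning score,
mapping quality = `round(60 * jaccard)`), and `self_coverage()` stabs the
rows back onto the reference to read out per-base copy number. On
synthetic copy-number fixtures this recovers the planted copy number
exactly for 2-4 copies. Per-base translation keeps the implementation
transparent; it is quadratic-ish in locus size and meant for extracted
loci, not whole chromosomes.

## 1D visualization

`bin_matrix()` lays nodes along the pangenome axis in id order (so the
picture reflects the current sort), divides the axis into
`ceiling(total/width)`-bp bins (the last may be partial), and aggregates
per path x bin: covered bases, mean along-path position, reverse-strand
base fraction, and mean depth. Depth here is the path's *own* step count
on each node — self-coverage, the quantity that exposes copy-number
differences between haplotypes — with all-paths depth behind a flag.
`render_1d()` paints one row per path and one column per bin, empty
cells white:

* `name` — hue from a deterministic byte-wise digest of the path name;
* `position` — light gray at the path start ramping to dark at its end;
* `strand` — black forward, red where a cell is majority
  reverse-complement;
* `depth` — a banded palette: white for no depth, gray for 1, red for 2,
  yellow for 3 or more, with band edges at 1.5 and 2.5 so fractional bin
  means fall to the nearest class.

A link track lists edges whose endpoint bins are not adjacent (the
threshold is exposed); those long-range links are what reveal structural
variants in an otherwise linear rendering. `draw_svg()` renders a 2D
layout as one segment per node plus thin edge lines in a fitted viewBox;
SVG keeps the renderer dependency-free and testable as XML.

## Synthetic graphs and what the tests do (and do not) show

All tests run on generated graphs with planted truth: permuted linear
chains (truth: the chain order), biallelic bubble backbones with
indel-like arms of unequal length (truth: each haplotype's allele
vector), copy-number loops where a query re-traverses a reference
segment `copies` times (truth: the copy number and duplicated interval;
the default geometry — 1 bp nodes, two-node leading flank, four-node
segment and trailing flank — reproduces the worked examples in the
documentation), a collapsed repeat whose reference visits one node twice
with distinct flanks (truth: the correct visit per query position), and
random walk-consistent graphs for fuzzing. One explicit seed drives each
generator and the caller's RNG state is restored afterwards;
regenerating with the same seed reproduces the canonical GFA
byte-identically.

The acceptance-style checks use 200 random graphs for GFA losslessness,
24 for sequence conservation under editing, 100 for the depth/degree
oracle comparison, five 50-node chains for PG-SGD recovery, 25 repeat
fixtures for liftover, and 2-4-copy loops for untangling — sizes chosen
so the whole suite stays interactive while still exercising every code
path. These fixtures emulate the *shapes* of real pangenome graphs, not
their content: node sequences are uniform random, bubbles are strictly
biallelic, and repeats have clean, fully distinct flanks. Passing tests
therefore demonstrate correctness of the algorithms under their stated
contracts, not robustness to the messiness of real assemblies (sequencing
artifacts, nested variation, centromeric repeat families with ambiguous
flanks).

## Known limitations

* Storage is plain R lists/environments, not succinct bit-packed
  vectors; the asymptotic storage contract is honored as record counts.
  Desk-scale graphs (up to ~10^4-10^5 nodes) are the intended regime.
* No parallel mutation; the locking contract is documented, not
  exercised.
* Untangle translates per base; use it on extracted loci.
* GFA `W` lines, GFAv2, rGFA, overlap CIGARs and BEDPE output are
  unsupported by design.
* 1D PG-SGD, like any stochastic layout, can in principle settle in a
  folded order on pathological inputs; the stress diagnostic makes such
  outcomes measurable.
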