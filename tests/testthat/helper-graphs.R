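# Shared fixtures and independent oracles. The oracles work at the GFA text
# level (re-deriving quantities from S/L/P records alone), so they share no
# code path with the graph model they check.

make_g1 <- function() vg_example_graph()

# structural equivalence up to node renumbering: same node-sequence multiset,
# same sizes, same path names and sequences
expect_graph_equivalent <- function(a, b) {
  expect_equal(vg_n_nodes(a), vg_n_nodes(b))
  expect_equal(vg_n_edges(a), vg_n_edges(b))
  seqs <- function(g) sort(vapply(vg_node_ids(g), function(id) vg_sequence(g, id),
                                  character(1)))
  expect_identical(seqs(a), seqs(b))
  expect_setequal(vg_paths(a), vg_paths(b))
  for (p in vg_paths(a)) {
    expect_identical(vg_path_sequence(a, p), vg_path_sequence(b, p))
  }
}

# --- text-level oracles ----------------------------------------------------

gfa_fields <- function(g) strsplit(write_gfa(g), "\t", fixed = TRUE)

# node depth per segment NAME, from P lines alone
oracle_depths <- function(g) {
  f <- gfa_fields(g)
  segs <- vapply(Filter(function(x) x[1] == "S", f), `[`, character(1), 2L)
  depth <- setNames(integer(length(segs)), segs)
  for (x in Filter(function(x) x[1] == "P", f)) {
    if (x[3] == "*") next
    ids <- sub("[+-]$", "", strsplit(x[3], ",", fixed = TRUE)[[1]])
    for (id in ids) depth[[id]] <- depth[[id]] + 1L
  }
  depth
}

# node degree per segment NAME, from L lines alone (bidirected identity:
# (a,s1,b,s2) == (b, flip s2, a, flip s1); self-loop counts once)
oracle_degrees <- function(g) {
  f <- gfa_fields(g)
  segs <- vapply(Filter(function(x) x[1] == "S", f), `[`, character(1), 2L)
  inc <- setNames(vector("list", length(segs)), segs)
  flip <- function(s) if (s == "+") "-" else "+"
  for (x in Filter(function(x) x[1] == "L", f)) {
    k1 <- paste(x[2], x[3], x[4], x[5])
    k2 <- paste(x[4], flip(x[5]), x[2], flip(x[3]))
    key <- min(k1, k2)
    inc[[x[2]]] <- union(inc[[x[2]]], key)
    inc[[x[4]]] <- union(inc[[x[4]]], key)
  }
  vapply(inc, length, integer(1))
}

# per-bp depth track along a path, from S lengths and the P line alone
oracle_depth_track <- function(g, path_name) {
  f <- gfa_fields(g)
  lens <- new.env(parent = emptyenv())
  for (x in Filter(function(x) x[1] == "S", f)) assign(x[2], nchar(x[3]), envir = lens)
  depth <- oracle_depths(g)
  for (x in Filter(function(x) x[1] == "P", f)) {
    if (x[2] != path_name) next
    ids <- sub("[+-]$", "", strsplit(x[3], ",", fixed = TRUE)[[1]])
    return(unlist(lapply(ids, function(id) rep(depth[[id]], get(id, envir = lens)))))
  }
  stop("path not found")
}

# package depth/degree keyed by segment display name, for oracle comparison
pkg_depths_by_name <- function(g) {
  ids <- vg_node_ids(g)
  setNames(vapply(ids, function(id) node_depth(g, id), integer(1)),
           vapply(ids, function(id) pangraphr:::seg_display_name(g, id), character(1)))
}

pkg_degrees_by_name <- function(g) {
  ids <- vg_node_ids(g)
  setNames(vapply(ids, function(id) node_degree(g, id), integer(1)),
           vapply(ids, function(id) pangraphr:::seg_display_name(g, id), character(1)))
}

spearman_vs_truth <- function(order, truth_order) {
  rk <- integer(0)
  rk[as.character(truth_order)] <- seq_along(truth_order)
  abs(stats::cor(rk[as.character(order)], seq_along(order), method = "spearman"))
}

random_fixture_pool <- function(n, seed0 = 1000) {
  lapply(seq_len(n), function(i) {
    kind <- i %% 4L
    if (kind == 0L) {
      fixture_random(n_nodes = 5L + (i %% 20L), n_paths = 1L + (i %% 4L),
                     seed = seed0 + i, named_segments = i %% 8L == 0L)$graph
    } else if (kind == 1L) {
      fixture_linear(n_nodes = 3L + (i %% 15L), node_len = 1L + (i %% 7L),
                     seed = seed0 + i)$graph
    } else if (kind == 2L) {
      fixture_bubble(n_bubbles = 1L + (i %% 4L), hap_count = 1L + (i %% 3L),
                     seed = seed0 + i)$graph
    } else {
      fixture_cnv(copies = 1L + (i %% 4L), seg_nodes = 2L + (i %% 3L),
                  node_len = 1L + (i %% 3L), seed = seed0 + i)$graph
    }
  })
}
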