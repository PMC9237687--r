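test_that("chop splits greedily and conserves path sequences", {
  g <- vg_new()
  vg_add_node(g, "ACGTACGTAC", 1)
  vg_add_path(g, "p"); vg_append_step(g, "p", "1+")
  gc <- vg_chop(g, 4)
  seqs <- vapply(vg_node_ids(gc), function(id) vg_sequence(gc, id), character(1))
  expect_identical(unname(seqs), c("ACGT", "ACGT", "AC"))
  expect_identical(vg_path_sequence(gc, "p"), "ACGTACGTAC")
  # idempotent below threshold
  g1 <- make_g1()
  gc1 <- vg_chop(g1, 4)
  expect_identical(write_gfa(gc1), write_gfa(g1))
})

test_that("chop handles reverse steps and keeps graphs valid", {
  g <- vg_new()
  vg_add_node(g, "ACGTTT", 1); vg_add_node(g, "GG", 2)
  vg_add_edge(g, "1+", "2+")
  vg_add_path(g, "fwd"); vg_append_step(g, "fwd", "1+"); vg_append_step(g, "fwd", "2+")
  vg_add_path(g, "rev"); vg_append_step(g, "rev", "2-"); vg_append_step(g, "rev", "1-")
  before <- vapply(vg_paths(g), function(p) vg_path_sequence(g, p), character(1))
  gc <- vg_chop(g, 2)
  expect_length(vg_validate(gc), 0L)
  expect_true(all(vapply(vg_node_ids(gc), function(id) nchar(vg_sequence(gc, id)),
                         integer(1)) <= 2L))
  after <- vapply(vg_paths(gc), function(p) vg_path_sequence(gc, p), character(1))
  expect_identical(after, before)
})

test_that("unchop merges a simple unitig and respects branching", {
  g <- vg_new()
  vg_add_node(g, "AC", 1); vg_add_node(g, "GT", 2)
  vg_add_edge(g, "1+", "2+")
  vg_add_path(g, "p"); vg_append_step(g, "p", "1+"); vg_append_step(g, "p", "2+")
  gu <- vg_unchop(g)
  expect_equal(vg_n_nodes(gu), 1L)
  expect_identical(vg_sequence(gu, vg_node_ids(gu)), "ACGT")
  expect_equal(pangraphr:::get_path_meta(gu, 1L)$step_count, 1L)
  # bubble junction of the toy graph is not merged
  g1 <- make_g1()
  expect_equal(vg_n_nodes(vg_unchop(g1)), 4L)
})

test_that("unchop(chop(k)) reaches the same normal form for several k", {
  g1 <- make_g1()
  norm <- vg_unchop(g1)
  for (k in c(1L, 2L, 3L, 5L)) {
    expect_graph_equivalent(vg_unchop(vg_chop(g1, k)), norm)
  }
  # and unchop is idempotent
  expect_graph_equivalent(vg_unchop(norm), norm)
})

test_that("chop/unchop conserve path sequences and length on random graphs", {
  for (g in random_fixture_pool(12, seed0 = 600)) {
    before <- vapply(vg_paths(g), function(p) vg_path_sequence(g, p), character(1))
    for (k in c(1L, 3L)) {
      gc <- vg_chop(g, k)
      expect_equal(vg_length(gc), vg_length(g))
      expect_identical(vapply(vg_paths(gc), function(p) vg_path_sequence(gc, p),
                              character(1)), before)
      gu <- vg_unchop(gc)
      expect_identical(vapply(vg_paths(gu), function(p) vg_path_sequence(gu, p),
                              character(1)), before)
      expect_length(vg_validate(gu), 0L)
    }
  }
})

test_that("extract selects step-touched nodes and splits path runs", {
  g <- make_g1()
  ex <- vg_extract(g, "x:4-7", ctx_steps = 0)
  expect_setequal(vg_node_ids(ex), c(2L, 4L))
  expect_identical(vg_path_sequence(ex, "x:4-7"), "ATT")
  expect_identical(vg_path_sequence(ex, "y:5-7"), "TT")
  # full range: y splits at the missing bubble arm; x keeps its name
  ex2 <- vg_extract(g, "x:0-7", ctx_steps = 0)
  expect_setequal(vg_node_ids(ex2), c(1L, 2L, 4L))
  expect_setequal(vg_paths(ex2), c("x", "y:0-4", "y:5-7"))
  expect_identical(vg_path_sequence(ex2, "y:0-4"), "ACGT")
  # saturation with large context
  ex3 <- vg_extract(g, "x:4-5", ctx_steps = 10)
  expect_equal(vg_n_nodes(ex3), 4L)
  expect_error(vg_extract(g, "nope:0-2"), "no path")
  expect_error(vg_extract(g, "x:5-3"), "cannot parse|invalid range")
})

test_that("extract subpath sequences are exact substrings of the originals", {
  for (g in random_fixture_pool(8, seed0 = 900)) {
    pnames <- vg_paths(g)
    pnames <- pnames[vapply(pnames, function(p) vg_path_length(g, p), integer(1)) >= 3L]
    if (length(pnames) == 0L) next
    p <- pnames[1]
    plen <- vg_path_length(g, p)
    full <- vg_path_sequence(g, p)
    ex <- vg_extract(g, data.frame(path = p, start = 1L, end = plen - 1L))
    for (sp in vg_paths(ex)) {
      sub <- vg_path_sequence(ex, sp)
      if (grepl(":[0-9]+-[0-9]+$", sp)) {
        rng <- pangraphr:::parse_path_range(sp)
        expect_identical(sub, substr(vg_path_sequence(g, rng$path),
                                     rng$start + 1L, rng$end))
      } else {
        expect_identical(sub, vg_path_sequence(g, sp))
      }
    }
  }
})

test_that("explode partitions components with ids and paths preserved", {
  g1 <- make_g1()
  expect_length(vg_explode(g1), 1L)
  iso <- vg_new(); vg_add_node(iso, "A", 1)
  un <- suppressMessages(vg_squeeze(list(g1, iso)))
  comps <- vg_explode(un)
  expect_length(comps, 2L)
  expect_equal(sum(vapply(comps, vg_n_nodes, integer(1))), vg_n_nodes(un))
})

test_that("component counts agree with an igraph recomputation", {
  for (g in random_fixture_pool(8, seed0 = 8100)) {
    ed <- vg_edges(g)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from_id), to = as.character(ed$to_id)),
      directed = FALSE,
      vertices = data.frame(name = as.character(vg_node_ids(g))))
    expect_equal(length(vg_explode(g)),
                 igraph::components(ig)$no)
    expect_equal(vg_stats(g)$n_components, igraph::components(ig)$no)
  }
})

test_that("squeeze shifts ids, renames collisions, and round-trips with explode", {
  g1 <- make_g1()
  expect_message(vg_squeeze(list(g1, g1)), "collision")
  sq <- suppressMessages(vg_squeeze(list(g1, g1)))
  expect_equal(vg_n_nodes(sq), 8L)
  expect_identical(vg_node_ids(sq), 1:8)
  expect_equal(vg_n_paths(sq), 4L)
  expect_setequal(vg_paths(sq), c("x", "y", "x#2", "y#2"))
  expect_identical(vg_path_sequence(sq, "x#2"), "ACGTATT")
  # identity on a single input
  expect_identical(write_gfa(vg_squeeze(list(g1))), write_gfa(g1))
  # explode(squeeze(a, b)) recovers the inputs when both are connected
  b <- fixture_bubble(1, 1, seed = 3)$graph
  parts <- vg_explode(vg_squeeze(list(g1, b)))
  expect_length(parts, 2L)
  expect_graph_equivalent(parts[[1]], g1)
})

test_that("prune drops nodes over the thresholds and re-emits fragments", {
  g1 <- make_g1()
  pr <- vg_prune(g1, max_depth = 1)
  expect_setequal(vg_node_ids(pr), c(2L, 3L))
  expect_setequal(vg_paths(pr), c("x:4-5", "y:4-5"))
  expect_identical(write_gfa(vg_prune(g1, max_depth = 99)), write_gfa(g1))
  pr2 <- vg_prune(g1, max_degree = 1)
  expect_true(all(vapply(vg_node_ids(pr2), function(id) node_degree(pr2, id),
                         integer(1)) <= 1L))
  expect_error(vg_prune(g1), "at least one")
})

test_that("apply_order relabels ids and conserves path sequences", {
  g1 <- make_g1()
  ao <- vg_apply_order(g1, c(4, 3, 2, 1))
  expect_identical(vg_sequence(ao, 1), "TT")
  tb <- pangraphr:::path_table(ao, "x")
  expect_identical(tb$node, c(4L, 3L, 1L))
  expect_identical(vg_path_sequence(ao, "x"), "ACGTATT")
  expect_identical(write_gfa(vg_apply_order(g1, 1:4)), write_gfa(g1))
  expect_error(vg_apply_order(g1, c(1, 2, 3)), "permutation")
  for (s in 1:5) {
    g <- random_fixture_pool(1, seed0 = 7000 + s)[[1]]
    before <- vapply(vg_paths(g), function(p) vg_path_sequence(g, p), character(1))
    set.seed(s)
    perm <- sample(vg_node_ids(g))
    ao2 <- vg_apply_order(g, perm)
    expect_identical(vapply(vg_paths(ao2), function(p) vg_path_sequence(ao2, p),
                            character(1)), before)
    expect_length(vg_validate(ao2), 0L)
  }
})

test_that("BED ranges drive extraction", {
  g1 <- make_g1()
  tf <- tempfile(fileext = ".bed")
  writeLines("x\t4\t7", tf)
  ex <- vg_extract(g1, read_bed(tf))
  expect_setequal(vg_node_ids(ex), c(2L, 4L))
})
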