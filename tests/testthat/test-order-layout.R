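test_that("topological order respects forward edges and breaks cycles", {
  g <- make_g1()
  expect_identical(topological_order(g), c(1L, 2L, 3L, 4L))
  g2 <- vg_new(); vg_add_node(g2, "AA", 1); vg_add_node(g2, "CC", 2)
  vg_add_edge(g2, "1+", "2+"); vg_add_edge(g2, "2+", "1+")
  expect_identical(topological_order(g2), c(1L, 2L))
  # permuted linear chain: every edge spans consecutive ranks
  l <- fixture_linear(30, 8, seed = 7)
  ord <- topological_order(l$graph)
  rk <- integer(0); rk[as.character(ord)] <- seq_along(ord)
  ed <- vg_edges(l$graph)
  expect_true(all(abs(rk[as.character(ed$from_id)] -
                        rk[as.character(ed$to_id)]) == 1L))
})

test_that("a single sampled term converges to its closed-form distance", {
  g <- vg_new()
  vg_add_node(g, "ACGT", 1); vg_add_node(g, "CA", 2)
  vg_add_edge(g, "1+", "2+")
  vg_add_path(g, "p"); vg_append_step(g, "p", "1+"); vg_append_step(g, "p", "2+")
  lay <- pg_sgd_1d(g, seed = 1)
  gap <- abs(lay$coords[["1"]] - lay$coords[["2"]])
  expect_lt(abs(gap - 3) / 3, 0.05)  # midpoint distance 4/2 + 2/2 = 3
})

test_that("1D PG-SGD recovers the planted chain order across seeds", {
  rhos <- vapply(1:5, function(s) {
    f <- fixture_linear(50, 10, seed = 100 + s)
    lay <- pg_sgd_1d(f$graph, seed = s)
    expect_lt(lay$stress_final, lay$stress_initial)
    spearman_vs_truth(layout_order(lay), f$truth$order)
  }, numeric(1))
  expect_gte(mean(rhos), 0.99)
})

test_that("PG-SGD is deterministic under a seed and errors without paths", {
  f <- fixture_linear(20, 5, seed = 11)
  a <- pg_sgd_1d(f$graph, seed = 4)
  b <- pg_sgd_1d(f$graph, seed = 4)
  expect_identical(a$coords, b$coords)
  g <- vg_new(); vg_add_node(g, "ACGT", 1)
  expect_error(pg_sgd_1d(g, seed = 1), "no non-empty path|no distance signal")
})

test_that("re-ordering by the learned 1D layout sorts the chain", {
  f <- fixture_linear(50, 10, seed = 42)
  lay <- pg_sgd_1d(f$graph, seed = 2)
  sorted <- vg_apply_order(f$graph, layout_order(lay))
  ed <- vg_edges(sorted)
  frac_adjacent <- mean(abs(ed$from_id - ed$to_id) == 1L)
  expect_gte(frac_adjacent, 0.95)
  expect_identical(vg_path_sequence(sorted, "chain"),
                   vg_path_sequence(f$graph, "chain"))
})

test_that("stress is zero for a perfect 1D fit and penalizes distortions", {
  g <- vg_new()
  lens <- c(4L, 2L, 6L, 3L)
  for (i in seq_along(lens)) {
    vg_add_node(g, strrep("A", lens[i]), i)
    if (i > 1L) vg_add_edge(g, vg_handle(i - 1L), vg_handle(i))
  }
  vg_add_path(g, "p")
  for (i in seq_along(lens)) vg_append_step(g, "p", vg_handle(i))
  mids <- cumsum(lens) - lens / 2
  perfect <- pangraphr:::layout_new(1L, setNames(as.numeric(mids),
                                                 as.character(seq_along(lens))),
                                    list(), 1L)
  expect_equal(layout_stress(g, perfect, seed = 9), 0)
  doubled <- pangraphr:::replace_coords(perfect, perfect$coords * 2)
  expect_gt(layout_stress(g, doubled, seed = 9), 0)
  # random placement is worse than the learned one
  f <- fixture_linear(30, 10, seed = 5)
  lay <- pg_sgd_1d(f$graph, seed = 5)
  set.seed(5)
  rnd <- pangraphr:::replace_coords(lay, setNames(runif(30, 0, 300),
                                                  names(lay$coords)))
  expect_gt(layout_stress(f$graph, rnd, seed = 7),
            layout_stress(f$graph, lay, seed = 7))
})

test_that("2D PG-SGD keeps chains extended and separates bubble arms", {
  f <- fixture_linear(20, 10, seed = 3)
  lay <- pg_sgd_2d(f$graph, seed = 2)
  expect_true(all(is.finite(lay$coords)))
  expect_lt(lay$stress_final, lay$stress_initial)
  ord <- f$truth$order
  pt <- function(id, e) lay$coords[paste0(id, ".", e), ]
  seg <- sum(vapply(ord, function(id) sqrt(sum((pt(id, 0) - pt(id, 1))^2)),
                    numeric(1)))
  gaps <- sum(vapply(seq_len(length(ord) - 1L), function(i) {
    sqrt(sum((pt(ord[i], 1) - pt(ord[i + 1L], 0))^2))
  }, numeric(1)))
  expect_lt(seg + gaps, 2 * vg_path_length(f$graph, "chain"))
  # bubble arms stay apart
  b <- fixture_bubble(1, 2, seed = 5, alleles = matrix(c(1, 2), 2, 1))
  lay2 <- pg_sgd_2d(b$graph, seed = 3)
  an <- b$truth$allele_nodes
  mid <- function(id) (lay2$coords[paste0(id, ".0"), ] +
                         lay2$coords[paste0(id, ".1"), ]) / 2
  expect_gt(sqrt(sum((mid(an[1, 1]) - mid(an[1, 2]))^2)), 1e-3)
  # single node: finite placement, zero stress
  g1 <- vg_new(); vg_add_node(g1, "ACGTACGT", 1)
  vg_add_path(g1, "p"); vg_append_step(g1, "p", "1+")
  lay3 <- pg_sgd_2d(g1, seed = 1)
  expect_true(all(is.finite(lay3$coords)))
  expect_equal(lay3$stress_final, 0)
})

test_that("layout TSV export carries one row per node", {
  f <- fixture_linear(10, 4, seed = 1)
  tf <- tempfile(fileext = ".tsv")
  write_layout_tsv(pg_sgd_1d(f$graph, seed = 1), tf)
  df <- read.delim(tf)
  expect_identical(names(df), c("node_id", "x"))
  expect_equal(nrow(df), 10L)
  write_layout_tsv(pg_sgd_2d(f$graph, iterations = 3, seed = 1), tf)
  df2 <- read.delim(tf)
  expect_identical(names(df2), c("node_id", "x", "y", "x_end", "y_end"))
  expect_equal(nrow(df2), 10L)
})
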