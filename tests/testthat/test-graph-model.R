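test_that("handles flip involutively and parse from strings", {
  h <- vg_handle(3, TRUE)
  expect_identical(handle_flip(handle_flip(h)), h)
  expect_identical(as_handle("12-"), vg_handle(12, TRUE))
  expect_identical(as_handle(7), vg_handle(7, FALSE))
  expect_error(as_handle("x+"), "cannot parse")
  expect_error(vg_handle(0), "positive")
})

test_that("delta encoding is the signed id difference and round-trips", {
  expect_identical(delta_encode(5, 3), 2L)
  expect_identical(delta_encode(3, 3), 0L)
  pairs <- expand.grid(from = 1:100, to = 1:100)
  expect_true(all(delta_decode(pairs$from, delta_encode(pairs$from, pairs$to)) ==
                    pairs$to))
})

test_that("nodes accumulate sequence, auto-ids continue past max_id", {
  g <- vg_new()
  h <- vg_add_node(g, "ACGT", 1)
  expect_identical(h, vg_handle(1, FALSE))
  expect_equal(vg_length(g), 4L)
  vg_add_node(g, "A", 7)
  h2 <- vg_add_node(g, "A")  # auto
  expect_equal(handle_id(h2), 8L)
  vg_add_node(g, "G")
  vg_add_node(g, "TT")
  expect_equal(vg_length(g), 4L + 1L + 1L + 1L + 2L)
  expect_error(vg_add_node(g, "AC", 1), "already present")
  expect_error(vg_add_node(g, ""), "non-empty")
  expect_error(vg_add_node(g, "ACGU"), "outside")
})

test_that("edges are bidirected, reciprocal, and idempotent", {
  g <- vg_new()
  vg_add_node(g, "AA", 1); vg_add_node(g, "CC", 2); vg_add_node(g, "GG", 3)
  vg_add_edge(g, "1+", "2+")
  vg_add_edge(g, "1+", "2+")
  expect_equal(vg_n_edges(g), 1L)
  expect_true(vg_has_edge(g, "2-", "1-"))  # flipped identity
  vg_add_edge(g, "2-", "1-")               # same edge again
  expect_equal(vg_n_edges(g), 1L)
  vg_add_edge(g, "3+", "3+")               # self-loop
  expect_equal(node_degree(g, 3), 1L)
  expect_error(vg_add_edge(g, "1+", "9+"), "missing node")
  expect_length(vg_validate(g), 0L)
})

test_that("appending steps maintains the doubly-linked list and path meta", {
  g <- make_g1()
  pm <- pangraphr:::get_path_meta(g, pangraphr:::resolve_path_id(g, "x"))
  expect_equal(pm$step_count, 3L)
  expect_equal(pm$head[1], 1L)
  expect_equal(pm$tail[1], 4L)
  tb <- pangraphr:::path_table(g, "x")
  expect_identical(tb$node, c(1L, 2L, 4L))
  # single-step path is both start and end
  vg_add_path(g, "solo")
  vg_append_step(g, "solo", "3+")
  nd <- pangraphr:::get_node(g, 3)
  st <- nd$steps[[length(nd$steps)]]
  expect_equal(st[3], 1L)  # is_start
  expect_equal(st[4], 1L)  # is_end
  expect_length(vg_validate(g), 0L)
  expect_error(vg_append_step(g, "nope", "1+"), "no path")
})

test_that("path sequences concatenate with reverse-complement steps", {
  g <- make_g1()
  expect_identical(vg_path_sequence(g, "x"), "ACGTATT")
  expect_identical(vg_path_sequence(g, "y"), "ACGTGTT")
  vg_add_path(g, "rc")
  vg_append_step(g, "rc", "2-")
  expect_identical(vg_path_sequence(g, "rc"), "T")
  vg_add_path(g, "pal")
  vg_append_step(g, "pal", "1-")
  expect_identical(vg_path_sequence(g, "pal"), "ACGT")  # palindromic node
})

test_that("validate reports constructed faults as data", {
  g <- make_g1()
  expect_length(vg_validate(g), 0L)
  # drop one direction of an edge
  nd <- pangraphr:::get_node(g, 2)
  nd$edges <- nd$edges[-1]
  assign("2", nd, envir = g$nodes)
  v <- vg_validate(g)
  expect_true(any(grepl("reciprocity", v)))
  # corrupt a next_rank
  g2 <- make_g1()
  nd1 <- pangraphr:::get_node(g2, 1)
  nd1$steps[[1]][8] <- 99L
  assign("1", nd1, envir = g2$nodes)
  v2 <- vg_validate(g2)
  expect_true(any(grepl("link symmetry: node 1 step 1", v2)))
})

test_that("empty paths are permitted and exempt from start/end flags", {
  g <- vg_new()
  vg_add_node(g, "ACGT", 1)
  vg_add_path(g, "empty")
  expect_length(vg_validate(g), 0L)
  expect_identical(vg_path_sequence(g, "empty"), "")
})

test_that("storage accounting matches the per-node record counts", {
  g <- make_g1()
  acc <- vg_storage_accounting(g)
  expect_equal(acc$edge_ints, 2L * acc$n_edge_records)
  expect_true(all(acc$step_ints <= 8L * acc$n_steps))
  depth <- vapply(acc$node, function(id) node_depth(g, id), integer(1))
  expect_equal(acc$n_steps, depth)
})

test_that("reverse complement agrees with Biostrings on random sequences", {
  set.seed(31)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:40, 1),
                      replace = TRUE), collapse = "")
    expect_identical(pangraphr:::revcomp(s),
                     as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("validate stays clean under fuzzed public mutations", {
  for (s in 1:10) {
    f <- fixture_random(n_nodes = 8L + s, n_paths = 2L, seed = 400L + s)
    expect_length(vg_validate(f$graph), 0L)
  }
})
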