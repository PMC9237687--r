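test_that("graph positions lift onto each traversing path step", {
  g <- make_g1()
  p <- graph_to_path_positions(g, 2, 0)
  expect_equal(nrow(p), 1L)
  expect_identical(p$path, "x")
  expect_equal(p$offset, 4L)
  expect_false(p$is_rev)
  p4 <- graph_to_path_positions(g, 4, 1)
  expect_equal(nrow(p4), 2L)
  expect_setequal(p4$path, c("x", "y"))
  expect_true(all(p4$offset == 6L))
  vg_add_node(g, "A", 9)
  expect_equal(nrow(graph_to_path_positions(g, 9, 0)), 0L)
  expect_error(graph_to_path_positions(g, 2, 5), "out of range")
  # reverse step: base offsets flip within the node
  gr <- vg_new(); vg_add_node(gr, "ACG", 1)
  vg_add_path(gr, "m"); vg_append_step(gr, "m", "1-")
  pr <- graph_to_path_positions(gr, 1, 0)
  expect_equal(pr$offset, 2L)
  expect_true(pr$is_rev)
})

test_that("step contexts collect node multisets within the bp radius", {
  r <- fixture_repeat(1)$graph
  expect_identical(sort(names(step_context(r, "q", 1, 1))), c("1", "2", "3"))
  expect_identical(sort(names(step_context(r, "r", 1, 1))), c("1", "2", "3"))
  expect_identical(sort(names(step_context(r, "r", 3, 1))), c("2", "3", "4"))
  ctx0 <- step_context(r, "q", 1, 0)
  expect_identical(names(ctx0), "2")
  expect_equal(unname(ctx0), 1L)
  # a repeated node within the window counts twice
  ctx_all <- step_context(r, "r", 2, 4)
  expect_equal(unname(ctx_all["2"]), 2L)
})

test_that("path jaccard uses multiset min/max semantics", {
  expect_equal(path_jaccard(c(`1` = 1, `2` = 1, `3` = 1),
                            c(`1` = 1, `2` = 1, `3` = 1)), 1)
  expect_equal(path_jaccard(c(`1` = 1, `2` = 1, `3` = 1),
                            c(`2` = 1, `3` = 1, `4` = 1)), 0.5)
  expect_equal(path_jaccard(c(`2` = 2), c(`2` = 1)), 0.5)
  expect_equal(path_jaccard(c(`1` = 1), c(`2` = 1)), 0)
  e <- path_jaccard(integer(0), integer(0))
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "undefined"))
})

test_that("translation picks the jaccard-optimal repeat visit", {
  r <- fixture_repeat(1)$graph
  tr <- translate_position(r, "q", 1, "r", radius = 1)
  expect_true(tr$hit)
  expect_equal(tr$offset, 1L)
  expect_equal(tr$jaccard, 1)
  expect_false(tr$is_rev)
  # the two visits score exactly 1.0 and 0.5 at radius 1
  qctx <- step_context(r, "q", 1, 1)
  expect_equal(path_jaccard(qctx, step_context(r, "r", 1, 1)), 1)
  expect_equal(path_jaccard(qctx, step_context(r, "r", 3, 1)), 0.5)
  # radius 0: contexts tie, smallest target offset wins
  tr0 <- translate_position(r, "q", 1, "r", radius = 0)
  expect_equal(tr0$offset, 1L)
  # unique visit on another path
  g <- make_g1()
  t6 <- translate_position(g, "x", 6, "y", radius = 10)
  expect_equal(t6$offset, 6L)
  expect_false(t6$is_rev)
  # unique visit on the same path is exact
  tself <- translate_position(g, "x", 6, "x", radius = 10)
  expect_equal(tself$jaccard, 1)
  # no-hit when the target never visits the node
  g2 <- make_g1()
  miss <- translate_position(g2, "x", 4, "y", radius = 10)  # node 2, y-free
  expect_false(miss$hit)
  expect_equal(miss$jaccard, 0)
})

test_that("the selected visit equals the brute-force optimum on repeat fixtures", {
  for (s in 1:20) {
    fx <- fixture_repeat(seed = s)
    g <- fx$graph
    for (qoff in fx$truth$query_offsets) {
      tr <- translate_position(g, "q", qoff, "r", radius = 1)
      # brute force: enumerate every target visit, score directly
      qtb <- pangraphr:::path_table(g, "q")
      qi <- findInterval(qoff, qtb$start)
      visits <- pangraphr:::path_visits_of_node(g, "r", qtb$node[qi],
                                                qoff - qtb$start[qi])
      qctx <- step_context(g, "q", qoff, 1)
      scores <- vapply(visits$offset, function(o) {
        as.numeric(path_jaccard(qctx, step_context(g, "r", o, 1)))
      }, numeric(1))
      best <- visits$offset[order(-scores, visits$offset)][1]
      expect_equal(tr$offset, best)
      expect_equal(tr$offset, fx$truth$true_ref_offsets[qoff + 1L])
    }
  }
})

test_that("untangle segments the CNV query at loop boundaries", {
  c1 <- fixture_cnv(2, 4, seed = 1)
  u <- vg_untangle(c1$graph, "q", "r", merge_dist = 1, radius = 2)
  expect_equal(nrow(u), 3L)
  expect_identical(u$query_start, c(0L, 6L, 10L))
  expect_identical(u$query_end, c(6L, 10L, 14L))
  expect_identical(u$target_start, c(0L, 2L, 6L))
  expect_identical(u$target_end, c(6L, 6L, 10L))
  expect_true(all(u$strand == "+"))
  # self-map: one full-length row, jaccard 1
  us <- vg_untangle(c1$graph, "r", "r", merge_dist = 1, radius = 2)
  expect_equal(nrow(us), 1L)
  expect_equal(us$target_start, 0L)
  expect_equal(us$target_end, 10L)
  expect_equal(us$jaccard, 1)
})

test_that("untangle flags inverted blocks with a minus strand row", {
  g <- vg_new()
  for (i in 1:5) vg_add_node(g, "AC", i)
  for (i in 1:4) vg_add_edge(g, vg_handle(i), vg_handle(i + 1L))
  vg_add_edge(g, "1+", "3-"); vg_add_edge(g, "3-", "5+")
  vg_add_path(g, "r"); for (i in 1:5) vg_append_step(g, "r", vg_handle(i))
  vg_add_path(g, "q")
  vg_append_step(g, "q", "1+"); vg_append_step(g, "q", "3-")
  vg_append_step(g, "q", "5+")
  u <- vg_untangle(g, "q", "r", merge_dist = 20, radius = 2)
  expect_equal(nrow(u), 3L)
  expect_identical(u$strand, c("+", "-", "+"))
})

test_that("untangle rows partition each query; self-coverage recovers copy number", {
  for (k in 2:4) {
    fx <- fixture_cnv(copies = k, seg_nodes = 4, seed = k)
    u <- vg_untangle(fx$graph, "q", "r", merge_dist = 1, radius = 2)
    qlen <- vg_path_length(fx$graph, "q")
    expect_equal(u$query_start[1], 0L)
    expect_equal(u$query_end[nrow(u)], qlen)
    expect_identical(u$query_start[-1], u$query_end[-nrow(u)])
    sc <- self_coverage(u, "r")
    di <- fx$truth$dup_interval
    expect_true(all(sc$value[sc$start >= di[1] & sc$end <= di[2]] == k))
    expect_true(all(sc$value[sc$end <= di[1] | sc$start >= di[2]] == 1L))
    # intervals tile the covered reference without overlap
    expect_true(all(sc$start[-1] == sc$end[-nrow(sc)]))
  }
  expect_equal(nrow(self_coverage(vg_untangle(make_g1(), character(0),
                                              character(0)), "r")), 0L)
})

test_that("PAF emission carries 12 columns and the jaccard tag", {
  c1 <- fixture_cnv(2, 4, seed = 1)
  u <- vg_untangle(c1$graph, "q", "r", merge_dist = 1, radius = 2)
  tf <- tempfile(fileext = ".paf")
  write_paf(u, tf)
  lines <- strsplit(readLines(tf), "\t", fixed = TRUE)
  expect_equal(length(lines), 3L)
  expect_true(all(vapply(lines, length, integer(1)) == 13L))
  expect_true(all(grepl("^jc:f:", vapply(lines, `[`, character(1), 13L))))
  mapq <- as.integer(vapply(lines, `[`, character(1), 12L))
  expect_true(all(mapq >= 0L & mapq <= 60L))
})
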