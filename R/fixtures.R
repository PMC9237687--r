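# Deterministic synthetic graph generators with planted ground truth. These
# emulate the *shapes* encountered in real pangenome graphs — linear
# backbones, allelic bubbles, copy-number loops, collapsed repeats — at desk
# scale, so ordering, untangling and liftover can be scored against known
# answers without external data. All randomness flows through one explicit
# seed; no global RNG state leaks (the caller's .Random.seed is restored).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Linear chain fixture
#'
#' A single linear component whose node ids are randomly permuted, so
#' ordering algorithms have real work to do; one forward path traverses the
#' whole chain. Truth: the node ids in chain order.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param node_len Sequence length per node in bp.
#' @param seed Integer seed.
#' @return A list with elements `graph` (a `vg_graph`) and `truth`
#'   (`kind`, `params`, `order` = ids along the chain, `path` = path name).
#' @export
fixture_linear <- function(n_nodes = 50, node_len = 10, seed = 1) {
  stopifnot(n_nodes >= 1)
  with_seed(seed, {
    ids <- sample.int(n_nodes)  # position i of the chain gets id ids[i]
    g <- vg_new()
    for (id in sort(ids)) vg_add_node(g, random_dna(node_len), id)
    for (i in seq_len(n_nodes - 1L)) {
      vg_add_edge(g, vg_handle(ids[i]), vg_handle(ids[i + 1L]))
    }
    vg_add_path(g, "chain")
    for (id in ids) vg_append_step(g, "chain", vg_handle(id))
    list(graph = g,
         truth = list(kind = "chain",
                      params = list(n_nodes = n_nodes, node_len = node_len, seed = seed),
                      order = ids, path = "chain"))
  })
}

#' Biallelic bubble fixture
#'
#' A backbone of anchors interleaved with `n_bubbles` biallelic bubbles.
#' The two alleles of each bubble differ in length (an indel-like bubble),
#' and each of `hap_count` haplotype paths picks one allele per bubble by a
#' seeded coin (or by an explicit `alleles` matrix). Truth: the per-path
#' allele vector.
#'
#' @param n_bubbles Number of bubbles (>= 1).
#' @param hap_count Number of haplotype paths.
#' @param seed Integer seed.
#' @param anchor_len,allele_len Anchor node length and the two allele lengths.
#' @param alleles Optional `hap_count x n_bubbles` matrix over `{1, 2}`
#'   forcing allele choices.
#' @return List `graph`, `truth` (with `alleles` matrix, `allele_nodes`
#'   2-column matrix of node ids per bubble, `anchor_nodes`).
#' @export
fixture_bubble <- function(n_bubbles = 3, hap_count = 2, seed = 1,
                           anchor_len = 8, allele_len = c(4, 7),
                           alleles = NULL) {
  stopifnot(n_bubbles >= 1, hap_count >= 1)
  with_seed(seed, {
    g <- vg_new()
    anchors <- integer(n_bubbles + 1L)
    allele_nodes <- matrix(0L, n_bubbles, 2)
    nid <- 0L
    for (b in seq_len(n_bubbles + 1L)) {
      nid <- nid + 1L; anchors[b] <- nid
      vg_add_node(g, random_dna(anchor_len), nid)
      if (b <= n_bubbles) {
        for (a in 1:2) {
          nid <- nid + 1L; allele_nodes[b, a] <- nid
          vg_add_node(g, random_dna(allele_len[a]), nid)
        }
      }
    }
    for (b in seq_len(n_bubbles)) {
      for (a in 1:2) {
        vg_add_edge(g, vg_handle(anchors[b]), vg_handle(allele_nodes[b, a]))
        vg_add_edge(g, vg_handle(allele_nodes[b, a]), vg_handle(anchors[b + 1L]))
      }
    }
    if (is.null(alleles)) {
      alleles <- matrix(sample(1:2, hap_count * n_bubbles, replace = TRUE),
                        hap_count, n_bubbles)
    }
    stopifnot(all(dim(alleles) == c(hap_count, n_bubbles)), all(alleles %in% 1:2))
    for (h in seq_len(hap_count)) {
      pname <- sprintf("hap%d", h)
      vg_add_path(g, pname)
      for (b in seq_len(n_bubbles)) {
        vg_append_step(g, pname, vg_handle(anchors[b]))
        vg_append_step(g, pname, vg_handle(allele_nodes[b, alleles[h, b]]))
      }
      vg_append_step(g, pname, vg_handle(anchors[n_bubbles + 1L]))
    }
    list(graph = g,
         truth = list(kind = "bubble",
                      params = list(n_bubbles = n_bubbles, hap_count = hap_count, seed = seed),
                      alleles = alleles, allele_nodes = allele_nodes,
                      anchor_nodes = anchors))
  })
}

#' Copy-number variant fixture
#'
#' A reference path runs once through flank + segment + flank; a query path
#' loops the segment `copies` times via a back edge, emulating a collapsed
#' copy-number variable locus. Truth: `copies` and the duplicated reference
#' interval in bp.
#'
#' @param copies Number of times the query traverses the segment (>= 1).
#' @param seg_nodes Nodes in the duplicated segment.
#' @param seed Integer seed.
#' @param node_len Node length in bp (1 reproduces the worked examples).
#' @param flank_left,flank_right Nodes in the leading / trailing flank.
#' @return List `graph`, `truth` (`copies`, `dup_interval` on the reference,
#'   `ref`, `query` path names).
#' @export
fixture_cnv <- function(copies = 2, seg_nodes = 4, seed = 1,
                        node_len = 1, flank_left = 2, flank_right = 4) {
  stopifnot(copies >= 1, seg_nodes >= 1, flank_left >= 1, flank_right >= 1)
  with_seed(seed, {
    flank <- flank_left
    n <- flank_left + seg_nodes + flank_right
    g <- vg_new()
    for (id in seq_len(n)) vg_add_node(g, random_dna(node_len), id)
    for (i in seq_len(n - 1L)) vg_add_edge(g, vg_handle(i), vg_handle(i + 1L))
    seg_start <- flank + 1L
    seg_end <- flank + seg_nodes
    if (copies > 1L) vg_add_edge(g, vg_handle(seg_end), vg_handle(seg_start))
    vg_add_path(g, "r")
    for (id in seq_len(n)) vg_append_step(g, "r", vg_handle(id))
    vg_add_path(g, "q")
    for (id in seq_len(seg_end)) vg_append_step(g, "q", vg_handle(id))
    if (copies > 1L) {
      for (k in seq_len(copies - 1L)) {
        for (id in seg_start:seg_end) vg_append_step(g, "q", vg_handle(id))
      }
    }
    if (seg_end < n) {
      for (id in (seg_end + 1L):n) vg_append_step(g, "q", vg_handle(id))
    }
    list(graph = g,
         truth = list(kind = "cnv",
                      params = list(copies = copies, seg_nodes = seg_nodes,
                                    node_len = node_len, flank_left = flank_left,
                                    flank_right = flank_right, seed = seed),
                      copies = copies,
                      dup_interval = c(flank * node_len, (flank + seg_nodes) * node_len),
                      ref = "r", query = "q"))
  })
}

#' Collapsed repeat fixture
#'
#' The reference visits one node twice with distinct flanks
#' (`r = 1,2,3,2,4` over 1 bp nodes); the query matches the first flank
#' (`q = 1,2,3`). Liftover of a query position on the repeated node must
#' pick the jaccard-optimal reference visit. Truth: the correct reference
#' offset for each query offset.
#'
#' @param seed Integer seed (varies node sequences only; the topology is fixed).
#' @return List `graph`, `truth` (`query_offsets`, `true_ref_offsets`,
#'   `repeat_node`, `visit_offsets` of the repeated node on the reference).
#' @export
fixture_repeat <- function(seed = 1) {
  with_seed(seed, {
    g <- vg_new()
    for (id in 1:4) vg_add_node(g, random_dna(1), id)
    vg_add_edge(g, "1+", "2+"); vg_add_edge(g, "2+", "3+")
    vg_add_edge(g, "3+", "2+"); vg_add_edge(g, "2+", "4+")
    vg_add_path(g, "r")
    for (h in c("1+", "2+", "3+", "2+", "4+")) vg_append_step(g, "r", h)
    vg_add_path(g, "q")
    for (h in c("1+", "2+", "3+")) vg_append_step(g, "q", h)
    list(graph = g,
         truth = list(kind = "repeat", params = list(seed = seed),
                      ref = "r", query = "q",
                      repeat_node = 2L, visit_offsets = c(1L, 3L),
                      query_offsets = 0:2, true_ref_offsets = 0:2))
  })
}

#' Random walk-consistent graph fixture
#'
#' A connected random bidirected graph whose paths are random walks along
#' existing edges (so editing operations that reason about adjacency see
#' realistic inputs). Used for fuzz / conservation testing.
#'
#' @param n_nodes Number of nodes.
#' @param n_paths Number of embedded paths.
#' @param seed Integer seed.
#' @param max_node_len Node sequences are 1..max_node_len bp.
#' @param extra_edges Edges added beyond the random spanning backbone.
#' @param named_segments If `TRUE`, segments get non-integer GFA names.
#' @return List `graph`, `truth` (kind `"random"`).
#' @export
fixture_random <- function(n_nodes = 12, n_paths = 3, seed = 1,
                           max_node_len = 6, extra_edges = 4,
                           named_segments = FALSE) {
  stopifnot(n_nodes >= 1)
  with_seed(seed, {
    g <- vg_new()
    for (id in seq_len(n_nodes)) {
      vg_add_node(g, random_dna(sample.int(max_node_len, 1)), id)
      if (named_segments) assign(nkey(id), sprintf("seg%03d", id), envir = g$seg_names)
    }
    if (n_nodes > 1L) {
      for (i in 2:n_nodes) {
        j <- sample.int(i - 1L, 1)
        vg_add_edge(g, vg_handle(j, runif(1) < 0.15), vg_handle(i, runif(1) < 0.15))
      }
      for (k in seq_len(extra_edges)) {
        ab <- sample.int(n_nodes, 2, replace = TRUE)
        vg_add_edge(g, vg_handle(ab[1], runif(1) < 0.2), vg_handle(ab[2], runif(1) < 0.2))
      }
    }
    for (p in seq_len(n_paths)) {
      pname <- sprintf("walk%d", p)
      vg_add_path(g, pname)
      h <- vg_handle(sample.int(n_nodes, 1), runif(1) < 0.2)
      vg_append_step(g, pname, h)
      len <- sample(1:(2L * n_nodes), 1)
      for (s in seq_len(len)) {
        nxt <- out_edges(g, h)
        if (length(nxt) == 0L) break
        h <- nxt[[sample.int(length(nxt), 1)]]
        vg_append_step(g, pname, h)
      }
    }
    list(graph = g,
         truth = list(kind = "random",
                      params = list(n_nodes = n_nodes, n_paths = n_paths, seed = seed)))
  })
}
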