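# The universal path coordinate system. Embedded paths serve as reference
# and query sequences: positions translate between graph and path space,
# and between paths, via path-jaccard context mapping — when a node is
# visited several times by the target path (a collapsed repeat), the visit
# whose node-id context best matches the query's context wins. Untangling
# segments query paths into linear blocks against a reference, exposing
# copy number and orientation in PAF form.

#' Lift a graph position onto path coordinates
#'
#' Reports one hit per path step on the node: the path, the 0-based bp
#' offset of the addressed base under that step's orientation, and the step
#' orientation.
#'
#' @param g A `vg_graph`.
#' @param node_id Node id.
#' @param offset 0-based offset into the node's forward sequence.
#' @return Data frame with columns `path`, `offset`, `is_rev` (possibly
#'   zero rows for a pathless node).
#' @examples
#' graph_to_path_positions(vg_example_graph(), 2, 0)  # x, 4, +
#' @export
graph_to_path_positions <- function(g, node_id, offset = 0) {
  nd <- get_node(g, node_id)
  len <- nchar(nd$seq)
  if (offset < 0 || offset >= len) {
    stop("offset ", offset, " out of range for node ", node_id, " (", len, " bp)")
  }
  hits <- list()
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    tb <- path_table(g, pid)
    on_node <- which(tb$node == node_id)
    for (i in on_node) {
      poff <- tb$start[i] + if (tb$rev[i]) (len - 1L - offset) else offset
      hits[[length(hits) + 1L]] <-
        data.frame(path = pm$name, offset = poff, is_rev = tb$rev[i])
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(path = character(0), offset = integer(0), is_rev = logical(0)))
  }
  do.call(rbind, hits)
}

#' Node-id context multiset around a path position
#'
#' The multiset of node ids of steps whose bp span intersects the closed
#' window `[offset - radius, offset + radius]` along the given path. The
#' context walks only that path.
#'
#' @param g A `vg_graph`.
#' @param path Path name or id.
#' @param offset 0-based bp position on the path.
#' @param radius Window radius in bp; 0 yields only the anchor step's node.
#' @return Named integer vector: node id -> multiplicity.
#' @export
step_context <- function(g, path, offset, radius) {
  tb <- path_table(g, path)
  plen <- sum(tb$len)
  if (offset < 0 || offset >= plen) {
    stop("offset ", offset, " out of range for path (", plen, " bp)")
  }
  lo <- offset - radius
  hi <- offset + radius
  hit <- tb$start <= hi & (tb$start + tb$len) > lo
  counts <- table(tb$node[hit])
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Multiset jaccard similarity of two contexts
#'
#' `|a n b| / |a u b|` with multiset semantics (elementwise min over max).
#' Two empty multisets score 0 with attribute `undefined = TRUE`.
#'
#' @param a,b Named integer vectors as returned by [step_context()].
#' @return Scalar in `[0, 1]`.
#' @examples
#' path_jaccard(c(`1` = 1, `2` = 1), c(`2` = 1, `3` = 1))  # 1/3
#' @export
path_jaccard <- function(a, b) {
  keys <- union(names(a), names(b))
  if (length(keys) == 0L) {
    return(structure(0, undefined = TRUE))
  }
  av <- ifelse(keys %in% names(a), a[keys], 0L)
  bv <- ifelse(keys %in% names(b), b[keys], 0L)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

# all steps of `path` on `node_id`, with the path offset of base
# `offset_in_node` under each visit
path_visits_of_node <- function(g, path, node_id, offset_in_node) {
  tb <- path_table(g, path)
  idx <- which(tb$node == node_id)
  len <- if (length(idx)) tb$len[idx[1]] else 0L
  data.frame(step = idx,
             rev = tb$rev[idx],
             offset = tb$start[idx] +
               ifelse(tb$rev[idx], len - 1L - offset_in_node, offset_in_node))
}

#' Translate a path position onto another path
#'
#' Locates the node under the query position, then chooses among the target
#' path's visits of that node the one whose context multiset maximizes the
#' path jaccard with the query context. Ties break to the smallest target
#' offset. A target path that never visits the node yields a no-hit result
#' (`hit = FALSE`), not an error.
#'
#' @param g A `vg_graph`.
#' @param query_path,target_path Path names or ids.
#' @param offset 0-based query bp position.
#' @param radius Context radius in bp (default 10 kbp, the scale at which
#'   repeat copies typically differ in their flanks).
#' @return A list: `hit`, `offset` (target bp), `is_rev` (strand of the
#'   mapping), `jaccard` (winning score).
#' @export
translate_position <- function(g, query_path, offset, target_path, radius = 10000) {
  qtb <- path_table(g, query_path)
  qlen <- sum(qtb$len)
  if (offset < 0 || offset >= qlen) {
    stop("offset ", offset, " out of range for query path (", qlen, " bp)")
  }
  qi <- findInterval(offset, qtb$start)
  node <- qtb$node[qi]
  off_in_node <- if (qtb$rev[qi]) {
    qtb$len[qi] - 1L - (offset - qtb$start[qi])
  } else {
    offset - qtb$start[qi]
  }
  qctx <- step_context(g, query_path, offset, radius)
  visits <- path_visits_of_node(g, target_path, node, off_in_node)
  if (nrow(visits) == 0L) {
    return(list(hit = FALSE, offset = NA_integer_, is_rev = NA, jaccard = 0))
  }
  scores <- vapply(visits$offset, function(toff) {
    as.numeric(path_jaccard(qctx, step_context(g, target_path, toff, radius)))
  }, numeric(1))
  best <- order(-scores, visits$offset)[1]
  list(hit = TRUE,
       offset = visits$offset[best],
       is_rev = xor(qtb$rev[qi], visits$rev[best]),
       jaccard = scores[best])
}

#' Untangle query paths against reference paths
#'
#' Maps every query base (via [translate_position()] against the
#' best-scoring reference path) to an implied reference coordinate and
#' strand, then cuts the query wherever the implied coordinate jumps by
#' more than `merge_dist`, the strand flips, or the best reference path
#' changes. Each maximal segment becomes one PAF-style mapping row whose
#' target interval spans its implied reference coordinates and whose
#' jaccard is the mean per-base winning score. Query stretches with no
#' reference coverage are emitted with an `NA` target and jaccard 0.
#'
#' @param g A `vg_graph`.
#' @param query_paths,ref_paths Character vectors of path names.
#' @param merge_dist Maximum tolerated jump in implied reference bp
#'   (default 10 kbp).
#' @param radius Context radius for the jaccard disambiguation.
#' @return Data frame of class `vg_untangle` with PAF-style columns
#'   `query`, `query_len`, `query_start`, `query_end`, `strand`, `target`,
#'   `target_len`, `target_start`, `target_end`, `jaccard`.
#' @export
vg_untangle <- function(g, query_paths, ref_paths, merge_dist = 10000,
                        radius = 10000) {
  rows <- list()
  ref_lens <- vapply(ref_paths, function(p) vg_path_length(g, p), integer(1))
  for (q in query_paths) {
    qlen <- vg_path_length(g, q)
    if (qlen == 0L) next
    ref_of <- character(qlen); ref_of[] <- NA_character_
    pos_of <- integer(qlen); pos_of[] <- NA_integer_
    rev_of <- logical(qlen)
    jac_of <- numeric(qlen)
    for (bp in seq_len(qlen) - 1L) {
      best <- NULL
      for (rp in ref_paths) {
        tr <- translate_position(g, q, bp, rp, radius)
        if (!tr$hit) next
        if (is.null(best) || tr$jaccard > best$jaccard ||
            (tr$jaccard == best$jaccard && tr$offset < best$offset)) {
          best <- tr; best$ref <- rp
        }
      }
      if (!is.null(best)) {
        ref_of[bp + 1L] <- best$ref
        pos_of[bp + 1L] <- best$offset
        rev_of[bp + 1L] <- best$is_rev
        jac_of[bp + 1L] <- best$jaccard
      }
    }
    # loop-back state: a base "advances" when its implied coordinate moves
    # past the farthest reference point reached so far (per ref and strand);
    # bases re-traversing already-covered reference are "looping". A segment
    # ends where the path loops back or where a loop-back region ends.
    adv <- logical(qlen)
    hi <- list(); lo <- list()
    for (i in seq_len(qlen)) {
      if (is.na(ref_of[i])) next
      key <- ref_of[i]
      if (!rev_of[i]) {
        h <- if (is.null(hi[[key]])) -Inf else hi[[key]]
        adv[i] <- pos_of[i] > h
        hi[[key]] <- max(h, pos_of[i])
      } else {
        l <- if (is.null(lo[[key]])) Inf else lo[[key]]
        adv[i] <- pos_of[i] < l
        lo[[key]] <- min(l, pos_of[i])
      }
    }
    # segment boundaries: ref change, strand flip, coordinate jump, or
    # advancing/looping state change
    cut <- logical(qlen)
    cut[1] <- TRUE
    for (i in 2:max(qlen, 2L)) {
      if (i > qlen) break
      if (is.na(ref_of[i]) != is.na(ref_of[i - 1L])) { cut[i] <- TRUE; next }
      if (is.na(ref_of[i])) next
      cut[i] <- ref_of[i] != ref_of[i - 1L] ||
        rev_of[i] != rev_of[i - 1L] ||
        abs(pos_of[i] - pos_of[i - 1L]) > merge_dist ||
        adv[i] != adv[i - 1L]
    }
    seg_id <- cumsum(cut)
    for (s in unique(seg_id)) {
      idx <- which(seg_id == s)
      qs <- idx[1] - 1L; qe <- idx[length(idx)]
      if (is.na(ref_of[idx[1]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, query_len = qlen, query_start = qs, query_end = qe,
          strand = NA_character_, target = NA_character_,
          target_len = NA_integer_, target_start = NA_integer_,
          target_end = NA_integer_, jaccard = 0)
      } else {
        rp <- ref_of[idx[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, query_len = qlen, query_start = qs, query_end = qe,
          strand = if (rev_of[idx[1]]) "-" else "+",
          target = rp, target_len = ref_lens[[rp]],
          target_start = min(pos_of[idx]), target_end = max(pos_of[idx]) + 1L,
          jaccard = mean(jac_of[idx]))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(query = character(0), query_len = integer(0),
               query_start = integer(0), query_end = integer(0),
               strand = character(0), target = character(0),
               target_len = integer(0), target_start = integer(0),
               target_end = integer(0), jaccard = numeric(0))
  }
  class(out) <- c("vg_untangle", class(out))
  out
}

#' Copy number over a reference from untangle rows
#'
#' For each reference base, the number of query segments covering it;
#' merged into run-length BED intervals (uncovered stretches are omitted).
#'
#' @param rows A `vg_untangle` data frame.
#' @param ref_name Reference path name to profile.
#' @return Data frame with columns `name`, `start`, `end`, `value` (copy
#'   number).
#' @export
self_coverage <- function(rows, ref_name) {
  rows <- rows[!is.na(rows$target) & rows$target == ref_name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), value = integer(0)))
  }
  rlen <- rows$target_len[1]
  cov <- integer(rlen)
  for (i in seq_len(nrow(rows))) {
    span <- (rows$target_start[i] + 1L):rows$target_end[i]
    cov[span] <- cov[span] + 1L
  }
  iv <- rle_intervals(ref_name, cov)
  iv[iv$value > 0L, , drop = FALSE]
}

#' Write untangle rows as PAF
#'
#' Twelve mandatory PAF columns plus a `jc:f:` tag carrying the jaccard
#' score. Residue-match and block-length columns are set from the interval
#' lengths; mapping quality is `round(jaccard * 60)`. Rows without a target
#' are skipped.
#'
#' @param rows A `vg_untangle` data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_paf <- function(rows, file) {
  rows <- rows[!is.na(rows$target), , drop = FALSE]
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    qspan <- r$query_end - r$query_start
    paste(r$query, r$query_len, r$query_start, r$query_end, r$strand,
          r$target, r$target_len, r$target_start, r$target_end,
          qspan, max(qspan, r$target_end - r$target_start),
          round(r$jaccard * 60),
          sprintf("jc:f:%g", r$jaccard), sep = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
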