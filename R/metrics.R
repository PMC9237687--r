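# Numerical interrogation of a graph: summary statistics, node depth and
# degree (as scalars and as run-length BED tracks over path positions),
# FASTA/BED flattening, per-path FASTA, and the pangenome matrix.

#' Node depth and degree
#'
#' Depth is the number of path steps on the node, across all paths and both
#' orientations. Degree is the number of distinct incident edges; a
#' self-loop counts once.
#'
#' @param g A `vg_graph`.
#' @param id Node id.
#' @return Non-negative integer.
#' @examples
#' g <- vg_example_graph()
#' node_depth(g, 1)   # 2
#' node_degree(g, 1)  # 2
#' @export
node_depth <- function(g, id) length(get_node(g, id)$steps)

#' @rdname node_depth
#' @export
node_degree <- function(g, id) {
  nd <- get_node(g, id)
  keys <- vapply(nd$edges, function(rec) {
    other <- delta_decode(id, rec[1])
    edge_key(id, rec[2] == 1L, other, rec[3] == 1L)
  }, character(1))
  length(unique(keys))
}

# run-length merge of a per-bp integer track into BED intervals
rle_intervals <- function(name, values) {
  if (length(values) == 0L) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), value = integer(0)))
  }
  r <- rle(values)
  ends <- cumsum(r$lengths)
  data.frame(name = name, start = c(0L, ends[-length(ends)]),
             end = ends, value = r$values)
}

per_step_track <- function(g, path, fn) {
  tb <- path_table(g, path)
  vals <- vapply(tb$node, fn, integer(1))
  rep(vals, tb$len)
}

#' Node depth / degree over the positions of a path
#'
#' For each base of the path, the value is the depth (resp. degree) of the
#' node under that base; adjacent equal values are merged into 0-based
#' half-open BED intervals that tile `[0, path length)`.
#'
#' @param g A `vg_graph`.
#' @param path Path name or id.
#' @return Data frame with columns `name`, `start`, `end`, `value`.
#' @export
depth_over_path <- function(g, path) {
  pm <- get_path_meta(g, resolve_path_id(g, path))
  rle_intervals(pm$name, per_step_track(g, path, function(n) node_depth(g, n)))
}

#' @rdname depth_over_path
#' @export
degree_over_path <- function(g, path) {
  pm <- get_path_meta(g, resolve_path_id(g, path))
  rle_intervals(pm$name, per_step_track(g, path, function(n) node_degree(g, n)))
}

#' Summary statistics of a graph
#'
#' Counts of nodes, edges, paths and connected components, the graph length
#' (sum of node sequence lengths) and the GC fraction of the graph sequence.
#' GC counts each node's sequence once — it is a property of the graph, not
#' weighted by path depth; `N` bases count in the denominator but not the
#' numerator. For an empty graph the GC fraction is reported as 0 with
#' `gc_defined = FALSE`.
#'
#' @param g A `vg_graph`.
#' @return A list of class `vg_stats` with fields `n_nodes`, `n_edges`,
#'   `n_paths`, `n_components`, `length_bp`, `gc_fraction`, `gc_defined`.
#' @examples
#' vg_stats(vg_example_graph())  # 4 nodes, 4 edges, 2 paths, gc 0.375
#' @export
vg_stats <- function(g) {
  ids <- vg_node_ids(g)
  len <- vg_length(g)
  gc <- 0
  if (len > 0L) {
    seqs <- paste(vapply(ids, function(id) vg_sequence(g, id), character(1)),
                  collapse = "")
    gc <- (nchar(gsub("[^GC]", "", seqs))) / nchar(seqs)
  }
  structure(list(n_nodes = length(ids),
                 n_edges = vg_n_edges(g),
                 n_paths = vg_n_paths(g),
                 n_components = length(unique(component_membership(g))),
                 length_bp = len,
                 gc_fraction = gc,
                 gc_defined = len > 0L),
            class = "vg_stats")
}

#' @export
print.vg_stats <- function(x, ...) {
  cat(write_stats_yaml(x), sep = "\n")
  invisible(x)
}

#' Emit graph statistics as YAML
#'
#' @param stats A `vg_stats` object (or a `vg_graph`, summarized first).
#' @param file Optional path to write to.
#' @return YAML text lines (invisibly when `file` is given).
#' @export
write_stats_yaml <- function(stats, file = NULL) {
  if (inherits(stats, "vg_graph")) stats <- vg_stats(stats)
  y <- yaml::as.yaml(list(n_nodes = stats$n_nodes, n_edges = stats$n_edges,
                          n_paths = stats$n_paths,
                          n_components = stats$n_components,
                          length_bp = stats$length_bp,
                          gc_fraction = stats$gc_fraction,
                          gc_defined = stats$gc_defined))
  out <- strsplit(y, "\n", fixed = TRUE)[[1]]
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Flatten a graph to FASTA plus BED
#'
#' Concatenates the forward-strand node sequences in the given order into a
#' single linear "pangenome" sequence, and reports two BED tables against
#' it: one row per node (its offset span) and one row per path step (its
#' span, path name, and step orientation as strand).
#'
#' @param g A `vg_graph`.
#' @param order Node order (defaults to ascending id, the current order).
#' @param name Name of the flattened sequence.
#' @return A list with `fasta` (named character vector of length 1),
#'   `nodes` and `steps` data frames.
#' @export
vg_flatten <- function(g, order = NULL, name = "flat") {
  ids <- vg_node_ids(g)
  if (is.null(order)) order <- ids
  order <- as.integer(order)
  if (!setequal(order, ids)) stop("order must be a permutation of node ids")
  seqs <- vapply(order, function(id) vg_sequence(g, id), character(1))
  lens <- nchar(seqs)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  names(offs) <- nkey(order)
  nodes <- data.frame(name = name, start = offs, end = offs + lens,
                      node = order, row.names = NULL)
  steps <- list()
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    tb <- path_table(g, pid)
    if (nrow(tb) == 0L) next
    o <- offs[nkey(tb$node)]
    steps[[length(steps) + 1L]] <-
      data.frame(name = name, start = o, end = o + tb$len,
                 path = pm$name, strand = ifelse(tb$rev, "-", "+"),
                 row.names = NULL)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else {
    data.frame(name = character(0), start = integer(0), end = integer(0),
               path = character(0), strand = character(0))
  }
  fasta <- paste(seqs, collapse = "")
  names(fasta) <- name
  list(fasta = fasta, nodes = nodes, steps = steps)
}

#' Path sequences as FASTA records
#'
#' @param g A `vg_graph`.
#' @param file Optional FASTA file to write.
#' @return Named character vector of path sequences (names = path names).
#' @export
paths_fasta <- function(g, file = NULL) {
  seqs <- vapply(g$path_order, function(pid) vg_path_sequence(g, pid), character(1))
  names(seqs) <- vg_paths(g)
  if (!is.null(file)) write_fasta(seqs, file)
  seqs
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param file Output path.
#' @param width Line wrap width.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 80L) {
  out <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    body <- if (nchar(s) == 0L) character(0) else {
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    }
    out <- c(out, paste0(">", nm), body)
  }
  writeLines(out, file)
  invisible(file)
}

#' The pangenome matrix as sparse triples
#'
#' Entry (path, node) is the number of steps of that path on that node;
#' zero entries are absent. Column sums over paths equal node depths.
#'
#' @param g A `vg_graph`.
#' @return Data frame with columns `path` (name), `path_index`, `node`
#'   (id), `count`.
#' @export
pangenome_matrix <- function(g) {
  rows <- list()
  pnames <- vg_paths(g)
  for (i in seq_along(g$path_order)) {
    tb <- path_table(g, g$path_order[i])
    if (nrow(tb) == 0L) next
    cnt <- table(tb$node)
    rows[[length(rows) + 1L]] <-
      data.frame(path = pnames[i], path_index = i,
                 node = as.integer(names(cnt)), count = as.integer(cnt),
                 row.names = NULL)
  }
  if (length(rows) == 0L) {
    return(data.frame(path = character(0), path_index = integer(0),
                      node = integer(0), count = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$path_index, out$node), , drop = FALSE]
}
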