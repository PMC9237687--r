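# Structural transformations. All of them return new graphs and conserve
# embedded path sequences exactly: chop/unchop re-segment node sequences
# without touching walks, extract/prune re-emit surviving path fragments as
# range-suffixed subpaths, explode/squeeze partition and unify components.

#' Break long nodes into pieces of at most `k` bp
#'
#' Every node longer than `k` is split greedily left-to-right into pieces of
#' `k` bp (the last piece may be shorter), chained with fresh ascending ids.
#' Edges re-attach to the terminal pieces and every path step through a
#' split node is replaced by the ordered piece steps (reversed for reverse
#' steps), so path sequences are unchanged.
#'
#' @param g A `vg_graph`.
#' @param k Maximum node length in bp (>= 1).
#' @return A new `vg_graph`.
#' @export
vg_chop <- function(g, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  ng <- vg_new()
  pieces <- new.env(parent = emptyenv())  # id -> integer vector of piece ids
  fresh <- g$max_id
  for (id in vg_node_ids(g)) {
    s <- vg_sequence(g, id)
    if (nchar(s) <= k) {
      vg_add_node(ng, s, id)
      assign(nkey(id), id, envir = pieces)
      nm <- nkey(id)
      if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
        assign(nm, get(nm, envir = g$seg_names), envir = ng$seg_names)
      }
    } else {
      starts <- seq(1L, nchar(s), by = k)
      ids <- fresh + seq_along(starts)
      fresh <- fresh + length(starts)
      for (i in seq_along(starts)) {
        vg_add_node(ng, substr(s, starts[i], min(starts[i] + k - 1L, nchar(s))), ids[i])
        if (i > 1L) vg_add_edge(ng, vg_handle(ids[i - 1L]), vg_handle(ids[i]))
      }
      assign(nkey(id), ids, envir = pieces)
    }
  }
  map_from <- function(h) {  # handle in "from" position: exits its 3' end
    ps <- get(nkey(h$id), envir = pieces)
    vg_handle(if (h$rev) ps[1] else ps[length(ps)], h$rev)
  }
  map_to <- function(h) {    # handle in "to" position: enters its 5' end
    ps <- get(nkey(h$id), envir = pieces)
    vg_handle(if (h$rev) ps[length(ps)] else ps[1], h$rev)
  }
  ed <- vg_edges(g)
  for (i in seq_len(nrow(ed))) {
    vg_add_edge(ng, map_from(vg_handle(ed$from_id[i], ed$from_rev[i])),
                map_to(vg_handle(ed$to_id[i], ed$to_rev[i])))
  }
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    vg_add_path(ng, pm$name)
    tb <- path_table(g, pid)
    for (i in seq_len(nrow(tb))) {
      ps <- get(nkey(tb$node[i]), envir = pieces)
      if (tb$rev[i]) ps <- rev(ps)
      for (p in ps) vg_append_step(ng, pm$name, vg_handle(p, tb$rev[i]))
    }
  }
  ng
}

# can the unique edge leaving handle h be merged away? returns the partner
# handle or NULL
merge_partner <- function(g, h) {
  outs <- out_edges(g, h)
  if (length(outs) != 1L) return(NULL)
  h2 <- outs[[1]]
  if (h2$id == h$id) return(NULL)
  ins <- out_edges(g, handle_flip(h2))
  if (length(ins) != 1L) return(NULL)
  # every step must traverse the junction in one pass:
  # steps on h's node along h must continue to h2; against h must come from h2
  a <- get_node(g, h$id)
  for (r in seq_along(a$steps)) {
    st <- a$steps[[r]]
    if ((st[.S_REV] == 1L) == h$rev) {
      if (st[.S_END] == 1L) return(NULL)
      nn <- delta_decode(h$id, st[.S_NDELTA])
      nrev <- get_node(g, nn)$steps[[st[.S_NRANK]]][.S_REV] == 1L
      if (nn != h2$id || nrev != h2$rev) return(NULL)
    } else {
      if (st[.S_START] == 1L) return(NULL)
      pn <- delta_decode(h$id, st[.S_PDELTA])
      prev <- get_node(g, pn)$steps[[st[.S_PRANK]]][.S_REV] == 1L
      if (pn != h2$id || prev == h2$rev) return(NULL)  # expect (h2, !h2$rev)
    }
  }
  b <- get_node(g, h2$id)
  for (r in seq_along(b$steps)) {
    st <- b$steps[[r]]
    if ((st[.S_REV] == 1L) == h2$rev) {
      if (st[.S_START] == 1L) return(NULL)
      pn <- delta_decode(h2$id, st[.S_PDELTA])
      prev <- get_node(g, pn)$steps[[st[.S_PRANK]]][.S_REV] == 1L
      if (pn != h$id || prev != h$rev) return(NULL)
    } else {
      if (st[.S_END] == 1L) return(NULL)
      nn <- delta_decode(h2$id, st[.S_NDELTA])
      nrev <- get_node(g, nn)$steps[[st[.S_NRANK]]][.S_REV] == 1L
      if (nn != h$id || nrev == h$rev) return(NULL)
    }
  }
  h2
}

hkey <- function(h) paste0(h$id, if (h$rev) "-" else "+")

unchop_once <- function(g) {
  follow <- new.env(parent = emptyenv())
  any_merge <- FALSE
  for (id in vg_node_ids(g)) {
    for (rev in c(FALSE, TRUE)) {
      h <- vg_handle(id, rev)
      p <- merge_partner(g, h)
      if (!is.null(p)) {
        assign(hkey(h), p, envir = follow)
        any_merge <- TRUE
      }
    }
  }
  if (!any_merge) return(list(graph = g, changed = FALSE))

  # assemble maximal chains of handles; each node lands in exactly one chain
  chained <- new.env(parent = emptyenv())
  chains <- list()
  for (id in vg_node_ids(g)) {
    if (exists(nkey(id), envir = chained, inherits = FALSE)) next
    chain <- list(vg_handle(id, FALSE))
    members <- id
    repeat {  # extend right
      k <- hkey(chain[[length(chain)]])
      if (!exists(k, envir = follow, inherits = FALSE)) break
      nxt <- get(k, envir = follow)
      if (nxt$id %in% members) break  # circular unitig: stop, keep open chain
      chain[[length(chain) + 1L]] <- nxt
      members <- c(members, nxt$id)
    }
    repeat {  # extend left: predecessor p satisfies follow[p] == chain[[1]]
      k <- hkey(handle_flip(chain[[1]]))
      if (!exists(k, envir = follow, inherits = FALSE)) break
      prv <- handle_flip(get(k, envir = follow))
      if (prv$id %in% members) break
      chain <- c(list(prv), chain)
      members <- c(members, prv$id)
    }
    if (chain[[1]]$id > chain[[length(chain)]]$id) {  # canonical orientation
      chain <- rev(lapply(chain, handle_flip))
    }
    for (m in members) assign(nkey(m), length(chains) + 1L, envir = chained)
    chains[[length(chains) + 1L]] <- chain
  }

  ng <- vg_new()
  chain_id <- integer(length(chains))
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    cid <- min(vapply(ch, handle_id, integer(1)))
    chain_id[ci] <- cid
    seqs <- vapply(ch, function(h) {
      s <- vg_sequence(g, h$id)
      if (h$rev) revcomp(s) else s
    }, character(1))
    vg_add_node(ng, paste(seqs, collapse = ""), cid)
    if (length(ch) == 1L) {
      nm <- nkey(cid)
      if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
        assign(nm, get(nm, envir = g$seg_names), envir = ng$seg_names)
      }
    }
  }
  chain_of <- function(id) get(nkey(id), envir = chained)
  # map a handle at a chain boundary to the merged node's strand; NULL if interior
  map_handle <- function(h, side) {  # side "from" (exits 3') or "to" (enters 5')
    ci <- chain_of(h$id); ch <- chains[[ci]]; m <- length(ch)
    first <- ch[[1]]; last <- ch[[m]]
    if (side == "from") {
      if (h$id == last$id && h$rev == last$rev) return(vg_handle(chain_id[ci], FALSE))
      if (h$id == first$id && h$rev == !first$rev) return(vg_handle(chain_id[ci], TRUE))
    } else {
      if (h$id == first$id && h$rev == first$rev) return(vg_handle(chain_id[ci], FALSE))
      if (h$id == last$id && h$rev == !last$rev) return(vg_handle(chain_id[ci], TRUE))
    }
    NULL
  }
  ed <- vg_edges(g)
  for (i in seq_len(nrow(ed))) {
    f <- map_handle(vg_handle(ed$from_id[i], ed$from_rev[i]), "from")
    t <- map_handle(vg_handle(ed$to_id[i], ed$to_rev[i]), "to")
    if (!is.null(f) && !is.null(t)) vg_add_edge(ng, f, t)
  }
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    vg_add_path(ng, pm$name)
    tb <- path_table(g, pid)
    i <- 1L
    while (i <= nrow(tb)) {
      ci <- chain_of(tb$node[i]); ch <- chains[[ci]]; m <- length(ch)
      first <- ch[[1]]; last <- ch[[m]]
      if (tb$node[i] == first$id && tb$rev[i] == first$rev) {
        vg_append_step(ng, pm$name, vg_handle(chain_id[ci], FALSE))
        i <- i + m
      } else if (tb$node[i] == last$id && tb$rev[i] == !last$rev) {
        vg_append_step(ng, pm$name, vg_handle(chain_id[ci], TRUE))
        i <- i + m
      } else {
        stop("internal error: path enters a unitig chain mid-way")
      }
    }
  }
  list(graph = ng, changed = TRUE)
}

#' Merge unitig chains into single nodes
#'
#' Repeatedly merges node pairs `a -> b` where `a`'s strand has `b` as its
#' unique successor, `b` has `a` as its unique predecessor, no other edges
#' meet the junction, and every embedded path crosses the junction in a
#' single consistent pass. The result has no further mergeable pair; path
#' sequences are unchanged. Merged nodes take the smallest id of their chain.
#'
#' @param g A `vg_graph`.
#' @return A new `vg_graph` in unitig normal form.
#' @export
vg_unchop <- function(g) {
  res <- list(graph = g, changed = TRUE)
  guard <- 0L
  while (res$changed) {
    res <- unchop_once(res$graph)
    guard <- guard + 1L
    if (guard > vg_n_nodes(g) + 2L) stop("unchop failed to reach a fixpoint")
  }
  res$graph
}

# induce the subgraph on a node set, re-emitting surviving path fragments as
# "name:start-end" subpaths (0-based half-open over the original path)
induce_subgraph <- function(g, keep_ids) {
  keep <- as.integer(keep_ids)
  ng <- vg_new()
  for (id in sort(keep)) {
    vg_add_node(ng, vg_sequence(g, id), id)
    nm <- nkey(id)
    if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
      assign(nm, get(nm, envir = g$seg_names), envir = ng$seg_names)
    }
  }
  ed <- vg_edges(g)
  for (i in seq_len(nrow(ed))) {
    if (ed$from_id[i] %in% keep && ed$to_id[i] %in% keep) {
      vg_add_edge(ng, vg_handle(ed$from_id[i], ed$from_rev[i]),
                  vg_handle(ed$to_id[i], ed$to_rev[i]))
    }
  }
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    tb <- path_table(g, pid)
    if (nrow(tb) == 0L) next
    inset <- tb$node %in% keep
    runs <- rle(inset)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in seq_along(runs$values)) {
      if (!runs$values[ri]) next
      i0 <- starts[ri]; i1 <- ends[ri]
      bp0 <- tb$start[i0]
      bp1 <- tb$start[i1] + tb$len[i1]
      # a run covering the entire path keeps its name; partial runs are
      # range-suffixed (0-based half-open over the original path)
      sub <- if (i0 == 1L && i1 == nrow(tb)) pm$name else {
        sprintf("%s:%d-%d", pm$name, bp0, bp1)
      }
      vg_add_path(ng, sub)
      for (i in i0:i1) vg_append_step(ng, sub, vg_handle(tb$node[i], tb$rev[i]))
    }
  }
  ng
}

parse_path_range <- function(x) {
  m <- regmatches(x, regexec("^(.*):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse path range '", x, "' (want name:start-end)")
  list(path = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

normalize_ranges <- function(ranges) {
  if (is.character(ranges)) {
    ranges <- lapply(ranges, parse_path_range)
    ranges <- data.frame(path = vapply(ranges, `[[`, character(1), "path"),
                         start = vapply(ranges, `[[`, integer(1), "start"),
                         end = vapply(ranges, `[[`, integer(1), "end"))
  }
  stopifnot(is.data.frame(ranges), all(c("path", "start", "end") %in% names(ranges)))
  ranges
}

#' Extract the subgraph under path ranges
#'
#' Selects the nodes touched by the steps of the given 0-based half-open
#' path ranges, expands the set by `ctx_steps` breadth-first hops over the
#' adjacency, and induces the subgraph. Every maximal run of any embedded
#' path through the selected nodes becomes a subpath named
#' `"name:start-end"` whose sequence is the corresponding substring of the
#' original path; a run covering the whole path keeps its original name.
#'
#' @param g A `vg_graph`.
#' @param ranges A data frame with columns `path`, `start`, `end`, or a
#'   character vector like `"x:4-7"` (see also [read_bed()]).
#' @param ctx_steps Non-negative number of context hops.
#' @return A new `vg_graph`.
#' @export
vg_extract <- function(g, ranges, ctx_steps = 0) {
  ranges <- normalize_ranges(ranges)
  keep <- integer(0)
  for (i in seq_len(nrow(ranges))) {
    tb <- path_table(g, ranges$path[i])
    plen <- sum(tb$len)
    s <- ranges$start[i]; e <- ranges$end[i]
    if (s < 0L || e > plen || s >= e) {
      stop(sprintf("invalid range %s:%d-%d (path length %d)",
                   ranges$path[i], s, e, plen))
    }
    hit <- tb$start < e & (tb$start + tb$len) > s
    keep <- union(keep, tb$node[hit])
  }
  frontier <- keep
  hops <- 0L
  while (hops < ctx_steps && length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(id) neighbor_ids(g, id))))
    frontier <- setdiff(nxt, keep)
    keep <- union(keep, frontier)
    hops <- hops + 1L
  }
  if (length(keep) == 0L) {
    warning("extraction selected no nodes; returning an empty graph")
    return(vg_new())
  }
  induce_subgraph(g, keep)
}

#' Split a graph into its connected components
#'
#' Components are computed over the undirected view of the bidirected
#' adjacency; node ids are preserved and each embedded path lies wholly in
#' one component.
#'
#' @param g A `vg_graph`.
#' @return List of `vg_graph`s, ordered by smallest contained node id.
#' @export
vg_explode <- function(g) {
  comp <- component_membership(g)
  if (length(comp) == 0L) return(list())
  lapply(sort(unique(comp)), function(ci) {
    ids <- as.integer(names(comp)[comp == ci])
    ng <- vg_new()
    for (id in sort(ids)) {
      vg_add_node(ng, vg_sequence(g, id), id)
      nm <- nkey(id)
      if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
        assign(nm, get(nm, envir = g$seg_names), envir = ng$seg_names)
      }
    }
    ed <- vg_edges(g)
    for (i in seq_len(nrow(ed))) {
      if (ed$from_id[i] %in% ids) {
        vg_add_edge(ng, vg_handle(ed$from_id[i], ed$from_rev[i]),
                    vg_handle(ed$to_id[i], ed$to_rev[i]))
      }
    }
    for (pid in g$path_order) {
      pm <- get_path_meta(g, pid)
      tb <- path_table(g, pid)
      if (nrow(tb) == 0L || !(tb$node[1] %in% ids)) next
      vg_add_path(ng, pm$name)
      for (i in seq_len(nrow(tb))) {
        vg_append_step(ng, pm$name, vg_handle(tb$node[i], tb$rev[i]))
      }
    }
    ng
  })
}

# component index per node, named by node id
component_membership <- function(g) {
  ids <- vg_node_ids(g)
  comp <- integer(0)
  seen <- new.env(parent = emptyenv())
  ci <- 0L
  for (id in ids) {
    if (exists(nkey(id), envir = seen, inherits = FALSE)) next
    ci <- ci + 1L
    queue <- id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (exists(nkey(cur), envir = seen, inherits = FALSE)) next
      assign(nkey(cur), ci, envir = seen)
      comp[nkey(cur)] <- ci
      queue <- c(queue, setdiff(neighbor_ids(g, cur),
                                as.integer(names(comp))))
    }
  }
  comp
}

#' Unify disjoint graphs into one
#'
#' Node ids of the second and later inputs are shifted by the running
#' maximum id; colliding path names are suffixed `"#i"` with the input index
#' and reported via a message.
#'
#' @param graphs Ordered list of `vg_graph`s.
#' @return A single `vg_graph`.
#' @export
vg_squeeze <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  ng <- vg_new()
  shift <- 0L
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    for (id in vg_node_ids(g)) {
      vg_add_node(ng, vg_sequence(g, id), id + shift)
      nm <- nkey(id)
      if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
        assign(nkey(id + shift), get(nm, envir = g$seg_names), envir = ng$seg_names)
      }
    }
    ed <- vg_edges(g)
    for (i in seq_len(nrow(ed))) {
      vg_add_edge(ng, vg_handle(ed$from_id[i] + shift, ed$from_rev[i]),
                  vg_handle(ed$to_id[i] + shift, ed$to_rev[i]))
    }
    for (pid in g$path_order) {
      pm <- get_path_meta(g, pid)
      nm <- pm$name
      if (exists(nm, envir = ng$path_names, inherits = FALSE)) {
        nm <- sprintf("%s#%d", nm, gi)
        message("path name collision: '", pm$name, "' renamed to '", nm, "'")
      }
      vg_add_path(ng, nm)
      tb <- path_table(g, pid)
      for (i in seq_len(nrow(tb))) {
        vg_append_step(ng, nm, vg_handle(tb$node[i] + shift, tb$rev[i]))
      }
    }
    shift <- ng$max_id
  }
  ng
}

#' Remove high-depth / high-degree nodes
#'
#' Drops every node whose depth exceeds `max_depth` or whose degree exceeds
#' `max_degree` (whichever thresholds are set), together with incident
#' edges. Surviving path fragments are re-emitted as range-suffixed
#' subpaths, as in [vg_extract()].
#'
#' @param g A `vg_graph`.
#' @param max_depth,max_degree Integer thresholds; at least one must be set.
#' @return A new `vg_graph`.
#' @export
vg_prune <- function(g, max_depth = NULL, max_degree = NULL) {
  if (is.null(max_depth) && is.null(max_degree)) {
    stop("set at least one of max_depth, max_degree")
  }
  keep <- vg_node_ids(g)
  if (!is.null(max_depth)) {
    keep <- keep[vapply(keep, function(id) node_depth(g, id), integer(1)) <= max_depth]
  }
  if (!is.null(max_degree)) {
    keep <- keep[vapply(keep, function(id) node_degree(g, id), integer(1)) <= max_degree]
  }
  induce_subgraph(g, keep)
}

#' Renumber nodes along a given order
#'
#' The i-th node of `order` receives id `i`; edges, steps and all delta
#' encodings are rewritten. Path sequences are unchanged.
#'
#' @param g A `vg_graph`.
#' @param order Permutation of the graph's node ids.
#' @return A new `vg_graph`.
#' @export
vg_apply_order <- function(g, order) {
  ids <- vg_node_ids(g)
  order <- as.integer(order)
  if (length(order) != length(ids) || !setequal(order, ids)) {
    stop("order must be a permutation of the graph's node ids")
  }
  newid <- integer(0)
  newid[nkey(order)] <- seq_along(order)
  remap <- function(id) newid[[nkey(id)]]
  ng <- vg_new()
  for (id in ids) {
    vg_add_node(ng, vg_sequence(g, id), remap(id))
    nm <- nkey(id)
    if (exists(nm, envir = g$seg_names, inherits = FALSE)) {
      assign(nkey(remap(id)), get(nm, envir = g$seg_names), envir = ng$seg_names)
    }
  }
  ed <- vg_edges(g)
  for (i in seq_len(nrow(ed))) {
    vg_add_edge(ng, vg_handle(remap(ed$from_id[i]), ed$from_rev[i]),
                vg_handle(remap(ed$to_id[i]), ed$to_rev[i]))
  }
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    vg_add_path(ng, pm$name)
    tb <- path_table(g, pid)
    for (i in seq_len(nrow(tb))) {
      vg_append_step(ng, pm$name, vg_handle(remap(tb$node[i]), tb$rev[i]))
    }
  }
  ng
}

#' Read a 3-column BED file as path ranges
#'
#' @param file Path to a BED file (0-based half-open intervals).
#' @return Data frame with columns `path`, `start`, `end`, usable with
#'   [vg_extract()].
#' @export
read_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(path = vapply(f, `[`, character(1), 1L),
             start = as.integer(vapply(f, `[`, character(1), 2L)),
             end = as.integer(vapply(f, `[`, character(1), 3L)))
}
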