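# In-memory variation graph V = (N, E, P).
#
# Each node record carries its sequence, its incident edges as delta-encoded
# "departing" views, and the vector of path steps crossing it. Steps form
# doubly-linked lists across node records; path heads/tails and the
# name -> path-id map are the only global path state.
#
# A step is a bare integer vector (fast, compact); field indices:
.S_PATH  <- 1L  # path id
.S_REV   <- 2L  # step orientation (0/1)
.S_START <- 3L  # first step of the path
.S_END   <- 4L  # last step of the path
.S_PDELTA <- 5L # delta to previous step's node (0 if start)
.S_PRANK  <- 6L # rank of previous step on that node (1-based, 0 if start)
.S_NDELTA <- 7L # delta to next step's node (0 if end)
.S_NRANK  <- 8L # rank of next step on that node (1-based, 0 if end)

# An edge record on node n is the edge expressed as departing n:
# c(delta = n - other, my_rev, other_rev). A non-self edge contributes one
# record to each endpoint (the second one in flipped view); a self-loop
# contributes up to two records on its node (one when the flipped view
# coincides). Mutation of at most two node records per operation; exclusive
# access, were it concurrent, would be acquired in ascending id order and
# released in descending order — the implementation is serial, which
# satisfies that contract vacuously.

nkey <- function(id) as.character(id)

#' Create an empty variation graph
#'
#' The graph is a mutable reference object (an environment): node- and
#' path-level mutators such as [vg_add_node()] and [vg_append_step()] modify
#' it in place, while structural transformations ([vg_chop()],
#' [vg_extract()], ...) return new graphs.
#'
#' @return An object of class `vg_graph`.
#' @examples
#' g <- vg_new()
#' vg_add_node(g, "ACGT", id = 1)
#' vg_n_nodes(g)
#' @export
vg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv())
  g$paths <- new.env(parent = emptyenv())       # path_id -> meta
  g$path_names <- new.env(parent = emptyenv())  # name -> path_id
  g$path_order <- integer(0)
  g$next_path_id <- 1L
  g$max_id <- 0L
  g$min_id <- NA_integer_
  g$seg_names <- new.env(parent = emptyenv())   # id -> original GFA segment name
  class(g) <- c("vg_graph", "environment")
  g
}

#' @export
print.vg_graph <- function(x, ...) {
  cat(sprintf("<variation graph: %d nodes, %d edges, %d paths, %d bp>\n",
              vg_n_nodes(x), vg_n_edges(x), vg_n_paths(x), vg_length(x)))
  invisible(x)
}

#' @export
summary.vg_graph <- function(object, ...) vg_stats(object)

has_node <- function(g, id) exists(nkey(id), envir = g$nodes, inherits = FALSE)

get_node <- function(g, id) {
  k <- nkey(id)
  if (!exists(k, envir = g$nodes, inherits = FALSE)) {
    stop("no node with id ", id, " in graph")
  }
  get(k, envir = g$nodes, inherits = FALSE)
}

#' Node ids of a graph
#' @param g A `vg_graph`.
#' @return Sorted integer vector of node ids.
#' @export
vg_node_ids <- function(g) sort(as.integer(ls(g$nodes, sorted = FALSE)))

#' Graph size accessors
#'
#' @param g A `vg_graph`.
#' @return Integer count, or total sequence length in bp for `vg_length()`.
#' @export
vg_n_nodes <- function(g) length(ls(g$nodes, sorted = FALSE))

#' @rdname vg_n_nodes
#' @export
vg_n_edges <- function(g) nrow(vg_edges(g))

#' @rdname vg_n_nodes
#' @export
vg_n_paths <- function(g) length(g$path_order)

#' @rdname vg_n_nodes
#' @export
vg_length <- function(g) {
  ids <- ls(g$nodes, sorted = FALSE)
  if (length(ids) == 0L) return(0L)
  sum(vapply(ids, function(k) nchar(get(k, envir = g$nodes)$seq), integer(1)))
}

#' Node sequence
#' @param g A `vg_graph`.
#' @param id Node id.
#' @return Forward-strand sequence of the node.
#' @export
vg_sequence <- function(g, id) get_node(g, id)$seq

#' Add a node to the graph
#'
#' @param g A `vg_graph` (modified in place).
#' @param sequence Non-empty DNA string over `A,C,G,T,N`.
#' @param id Positive integer id, or `NULL` to auto-assign `max_id + 1`.
#' @return The forward handle of the new node, invisibly.
#' @export
vg_add_node <- function(g, sequence, id = NULL) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    stop("node sequence must be a single non-empty string")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("node sequence contains characters outside {A,C,G,T,N}")
  }
  if (is.null(id)) id <- g$max_id + 1L
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stop("node id must be a positive integer")
  if (has_node(g, id)) stop("node id ", id, " already present in graph")
  assign(nkey(id), list(id = id, seq = sequence, edges = list(), steps = list()),
         envir = g$nodes)
  if (id > g$max_id) g$max_id <- id
  if (is.na(g$min_id) || id < g$min_id) g$min_id <- id
  invisible(vg_handle(id, FALSE))
}

# canonical directed form of an edge: (f, t) vs (flip(t), flip(f)), keep the
# lexicographically smaller (by from id, from rev, to id, to rev)
edge_canonical <- function(fid, frev, tid, trev) {
  a <- c(fid, frev, tid, trev)
  b <- c(tid, !trev, fid, !frev)
  lt <- function(u, v) {
    for (i in seq_along(u)) {
      if (u[i] < v[i]) return(TRUE)
      if (u[i] > v[i]) return(FALSE)
    }
    FALSE
  }
  if (lt(as.numeric(b), as.numeric(a))) b else a
}

edge_key <- function(fid, frev, tid, trev) {
  paste(edge_canonical(fid, frev, tid, trev), collapse = ":")
}

# records describing edge (f -> t) as stored on each endpoint
edge_records <- function(fid, frev, tid, trev) {
  recs <- list(list(node = fid, rec = c(delta_encode(fid, tid), as.integer(frev), as.integer(trev))))
  flip_rec <- c(delta_encode(tid, fid), as.integer(!trev), as.integer(!frev))
  if (fid != tid) {
    recs[[2]] <- list(node = tid, rec = flip_rec)
  } else if (!identical(recs[[1]]$rec, flip_rec)) {
    recs[[2]] <- list(node = tid, rec = flip_rec)
  }
  recs
}

#' Test for an edge between two handles
#'
#' Edges are bidirected: `(a, b)` is the same edge as `(flip(b), flip(a))`.
#'
#' @param g A `vg_graph`.
#' @param from,to Handles (anything [as_handle()] accepts).
#' @return Logical.
#' @export
vg_has_edge <- function(g, from, to) {
  f <- as_handle(from); t <- as_handle(to)
  if (!has_node(g, f$id) || !has_node(g, t$id)) return(FALSE)
  want <- edge_key(f$id, f$rev, t$id, t$rev)
  nd <- get_node(g, f$id)
  for (rec in nd$edges) {
    other <- delta_decode(f$id, rec[1])
    if (edge_key(f$id, rec[2] == 1L, other, rec[3] == 1L) == want) return(TRUE)
  }
  FALSE
}

#' Add a bidirected edge between two node strands
#'
#' Stored reciprocally on both node records; re-adding an existing edge
#' (including its flipped form) is a no-op.
#'
#' @param g A `vg_graph` (modified in place).
#' @param from,to Handles.
#' @return `g`, invisibly.
#' @export
vg_add_edge <- function(g, from, to) {
  f <- as_handle(from); t <- as_handle(to)
  if (!has_node(g, f$id)) stop("edge endpoint refers to missing node ", f$id)
  if (!has_node(g, t$id)) stop("edge endpoint refers to missing node ", t$id)
  if (vg_has_edge(g, f, t)) return(invisible(g))
  for (er in edge_records(f$id, f$rev, t$id, t$rev)) {
    k <- nkey(er$node)
    nd <- get(k, envir = g$nodes)
    nd$edges[[length(nd$edges) + 1L]] <- er$rec
    assign(k, nd, envir = g$nodes)
  }
  invisible(g)
}

#' Enumerate the edges of a graph
#'
#' @param g A `vg_graph`.
#' @return A data frame with columns `from_id`, `from_rev`, `to_id`, `to_rev`
#'   (one row per distinct bidirected edge, in canonical orientation), sorted.
#' @export
vg_edges <- function(g) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (id in vg_node_ids(g)) {
    nd <- get_node(g, id)
    for (rec in nd$edges) {
      other <- delta_decode(id, rec[1])
      can <- edge_canonical(id, rec[2] == 1L, other, rec[3] == 1L)
      key <- paste(can, collapse = ":")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- can
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from_id = integer(0), from_rev = logical(0),
                      to_id = integer(0), to_rev = logical(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(from_id = as.integer(m[, 1]), from_rev = as.logical(m[, 2]),
                   to_id = as.integer(m[, 3]), to_rev = as.logical(m[, 4]))
  df[order(df$from_id, df$to_id, df$from_rev, df$to_rev), , drop = FALSE]
}

# handles reachable by departing from handle h (follow its 3' end)
out_edges <- function(g, h) {
  h <- as_handle(h)
  nd <- get_node(g, h$id)
  res <- list()
  for (rec in nd$edges) {
    if ((rec[2] == 1L) == h$rev) {
      res[[length(res) + 1L]] <- vg_handle(delta_decode(h$id, rec[1]), rec[3] == 1L)
    }
  }
  res
}

# all neighbor node ids regardless of orientation
neighbor_ids <- function(g, id) {
  nd <- get_node(g, id)
  unique(vapply(nd$edges, function(rec) delta_decode(id, rec[1]), integer(1)))
}

## ---- paths ---------------------------------------------------------------

resolve_path_id <- function(g, path) {
  if (is.character(path)) {
    if (!exists(path, envir = g$path_names, inherits = FALSE)) {
      stop("no path named '", path, "' in graph")
    }
    return(get(path, envir = g$path_names))
  }
  pid <- as.integer(path)
  if (!exists(nkey(pid), envir = g$paths, inherits = FALSE)) {
    stop("no path with id ", pid, " in graph")
  }
  pid
}

get_path_meta <- function(g, pid) get(nkey(pid), envir = g$paths)

#' Create an empty path
#'
#' @param g A `vg_graph` (modified in place).
#' @param name Unique path name.
#' @return The integer path id, invisibly.
#' @export
vg_add_path <- function(g, name) {
  name <- as.character(name)
  if (exists(name, envir = g$path_names, inherits = FALSE)) {
    stop("path name '", name, "' already present in graph")
  }
  pid <- g$next_path_id
  g$next_path_id <- pid + 1L
  assign(nkey(pid), list(path_id = pid, name = name,
                         head = c(NA_integer_, NA_integer_),
                         tail = c(NA_integer_, NA_integer_),
                         step_count = 0L),
         envir = g$paths)
  assign(name, pid, envir = g$path_names)
  g$path_order <- c(g$path_order, pid)
  invisible(pid)
}

#' Path names in creation order
#' @param g A `vg_graph`.
#' @return Character vector.
#' @export
vg_paths <- function(g) {
  vapply(g$path_order, function(pid) get_path_meta(g, pid)$name, character(1))
}

#' Append a step to a path
#'
#' The new step becomes the path tail; the previous tail's end flag is
#' cleared and the doubly-linked next/prev fields of both steps are repaired.
#' The operation touches at most two node records.
#'
#' @param g A `vg_graph` (modified in place).
#' @param path Path name or id.
#' @param h Handle to visit.
#' @return Invisibly, `c(node_id, rank)` locating the new step.
#' @export
vg_append_step <- function(g, path, h) {
  pid <- resolve_path_id(g, path)
  h <- as_handle(h)
  if (!has_node(g, h$id)) stop("step refers to missing node ", h$id)
  pm <- get_path_meta(g, pid)
  k <- nkey(h$id)
  nd <- get(k, envir = g$nodes)
  rank <- length(nd$steps) + 1L
  if (pm$step_count == 0L) {
    step <- c(pid, as.integer(h$rev), 1L, 1L, 0L, 0L, 0L, 0L)
    pm$head <- c(h$id, rank)
  } else {
    tn <- pm$tail[1]; tr <- pm$tail[2]
    tk <- nkey(tn)
    tnd <- get(tk, envir = g$nodes)
    tstep <- tnd$steps[[tr]]
    tstep[.S_END] <- 0L
    tstep[.S_NDELTA] <- delta_encode(tn, h$id)
    tstep[.S_NRANK] <- rank
    tnd$steps[[tr]] <- tstep
    assign(tk, tnd, envir = g$nodes)
    if (tn == h$id) nd <- get(k, envir = g$nodes)  # same record; re-fetch
    step <- c(pid, as.integer(h$rev), 0L, 1L,
              delta_encode(h$id, tn), tr, 0L, 0L)
  }
  nd$steps[[rank]] <- step
  assign(k, nd, envir = g$nodes)
  pm$tail <- c(h$id, rank)
  pm$step_count <- pm$step_count + 1L
  assign(nkey(pid), pm, envir = g$paths)
  invisible(c(node_id = h$id, rank = rank))
}

# walk a path; returns data.frame(node, rank, rev, start, len) in step order,
# start = 0-based bp offset of the step along the path
path_table <- function(g, path) {
  pid <- resolve_path_id(g, path)
  pm <- get_path_meta(g, pid)
  n <- pm$step_count
  node <- integer(n); rank <- integer(n); rev <- logical(n); len <- integer(n)
  if (n > 0L) {
    cur <- pm$head
    for (i in seq_len(n)) {
      nd <- get_node(g, cur[1])
      if (cur[2] < 1L || cur[2] > length(nd$steps)) {
        stop("broken step chain in path '", pm$name, "': rank ", cur[2],
             " out of range on node ", cur[1])
      }
      st <- nd$steps[[cur[2]]]
      node[i] <- cur[1]; rank[i] <- cur[2]
      rev[i] <- st[.S_REV] == 1L; len[i] <- nchar(nd$seq)
      if (st[.S_END] == 1L) {
        if (i != n) stop("broken step chain in path '", pm$name,
                         "': premature end flag at step ", i)
        break
      }
      if (i == n) stop("broken step chain in path '", pm$name,
                       "': no end flag after ", n, " steps")
      cur <- c(delta_decode(cur[1], st[.S_NDELTA]), st[.S_NRANK])
    }
  }
  start <- if (n > 0L) cumsum(c(0L, len[-n])) else integer(0)
  data.frame(node = node, rank = rank, rev = rev, start = start, len = len)
}

#' Path length in bp
#' @param g A `vg_graph`.
#' @param path Path name or id.
#' @return Integer number of bases.
#' @export
vg_path_length <- function(g, path) {
  tb <- path_table(g, path)
  sum(tb$len)
}

#' Reconstruct the DNA sequence of an embedded path
#'
#' Concatenates node sequences along the path's steps, reverse-complementing
#' where a step traverses the reverse strand.
#'
#' @param g A `vg_graph`.
#' @param path Path name or id.
#' @return A DNA string.
#' @examples
#' g <- vg_example_graph()
#' vg_path_sequence(g, "x")  # "ACGTATT"
#' @export
vg_path_sequence <- function(g, path) {
  tb <- path_table(g, path)
  if (nrow(tb) == 0L) return("")
  pieces <- character(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    s <- get_node(g, tb$node[i])$seq
    pieces[i] <- if (tb$rev[i]) revcomp(s) else s
  }
  paste(pieces, collapse = "")
}

#' The toy graph used throughout the documentation
#'
#' Four nodes (`1:"ACGT"`, `2:"A"`, `3:"G"`, `4:"TT"`) forming a single
#' bubble, with two embedded haplotype paths `x = 1+,2+,4+` and
#' `y = 1+,3+,4+`.
#'
#' @return A `vg_graph`.
#' @export
vg_example_graph <- function() {
  g <- vg_new()
  vg_add_node(g, "ACGT", 1); vg_add_node(g, "A", 2)
  vg_add_node(g, "G", 3);    vg_add_node(g, "TT", 4)
  vg_add_edge(g, "1+", "2+"); vg_add_edge(g, "1+", "3+")
  vg_add_edge(g, "2+", "4+"); vg_add_edge(g, "3+", "4+")
  vg_add_path(g, "x")
  for (h in c("1+", "2+", "4+")) vg_append_step(g, "x", h)
  vg_add_path(g, "y")
  for (h in c("1+", "3+", "4+")) vg_append_step(g, "y", h)
  g
}

## ---- validation ----------------------------------------------------------

#' Check all structural invariants of a graph
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the graph is internally consistent (edge reciprocity, step link
#' symmetry, path head/tail flags, step-count accounting).
#'
#' @param g A `vg_graph`.
#' @return Character vector of human-readable violation descriptions.
#' @export
vg_validate <- function(g) {
  bad <- character(0)
  ids <- vg_node_ids(g)
  for (id in ids) {
    nd <- get_node(g, id)
    if (nchar(nd$seq) < 1L || grepl("[^ACGTN]", nd$seq)) {
      bad <- c(bad, sprintf("node %d: invalid sequence", id))
    }
    seen <- character(0)
    for (rec in nd$edges) {
      other <- delta_decode(id, rec[1])
      rk <- paste(rec, collapse = ":")
      if (rk %in% seen) bad <- c(bad, sprintf("node %d: duplicate edge record", id))
      seen <- c(seen, rk)
      if (!has_node(g, other)) {
        bad <- c(bad, sprintf("node %d: edge to missing node %d", id, other))
        next
      }
      if (other != id) {
        # edge reciprocity: flipped view must sit on the other node
        want <- c(delta_encode(other, id), as.integer(!(rec[3] == 1L)),
                  as.integer(!(rec[2] == 1L)))
        ond <- get_node(g, other)
        found <- any(vapply(ond$edges, function(r) identical(r, want), logical(1)))
        if (!found) {
          bad <- c(bad, sprintf("edge reciprocity: node %d lists edge to %d with no reciprocal record",
                                id, other))
        }
      }
    }
    for (r in seq_along(nd$steps)) {
      st <- nd$steps[[r]]
      if (!exists(nkey(st[.S_PATH]), envir = g$paths, inherits = FALSE)) {
        bad <- c(bad, sprintf("node %d step %d: unknown path id %d", id, r, st[.S_PATH]))
        next
      }
      if (st[.S_END] != 1L) {
        nn <- delta_decode(id, st[.S_NDELTA]); nr <- st[.S_NRANK]
        ok <- has_node(g, nn)
        if (ok) {
          nnd <- get_node(g, nn)
          ok <- nr >= 1L && nr <= length(nnd$steps)
          if (ok) {
            nxt <- nnd$steps[[nr]]
            ok <- nxt[.S_PATH] == st[.S_PATH] && nxt[.S_START] != 1L &&
              delta_decode(nn, nxt[.S_PDELTA]) == id && nxt[.S_PRANK] == r
          }
        }
        if (!ok) bad <- c(bad, sprintf("link symmetry: node %d step %d has inconsistent next link", id, r))
      }
      if (st[.S_START] != 1L) {
        pn <- delta_decode(id, st[.S_PDELTA]); pr <- st[.S_PRANK]
        ok <- has_node(g, pn)
        if (ok) {
          pnd <- get_node(g, pn)
          ok <- pr >= 1L && pr <= length(pnd$steps)
          if (ok) {
            prv <- pnd$steps[[pr]]
            ok <- prv[.S_PATH] == st[.S_PATH] && prv[.S_END] != 1L &&
              delta_decode(pn, prv[.S_NDELTA]) == id && prv[.S_NRANK] == r
          }
        }
        if (!ok) bad <- c(bad, sprintf("link symmetry: node %d step %d has inconsistent prev link", id, r))
      }
    }
  }
  total_steps <- 0L
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    total_steps <- total_steps + pm$step_count
    if (pm$step_count == 0L) next  # empty paths permitted, exempt from flags
    hd <- pm$head; tl <- pm$tail
    ok_head <- has_node(g, hd[1]) && hd[2] >= 1L &&
      hd[2] <= length(get_node(g, hd[1])$steps) &&
      get_node(g, hd[1])$steps[[hd[2]]][.S_START] == 1L
    if (!ok_head) bad <- c(bad, sprintf("path '%s': head does not resolve to a start step", pm$name))
    ok_tail <- has_node(g, tl[1]) && tl[2] >= 1L &&
      tl[2] <= length(get_node(g, tl[1])$steps) &&
      get_node(g, tl[1])$steps[[tl[2]]][.S_END] == 1L
    if (!ok_tail) bad <- c(bad, sprintf("path '%s': tail does not resolve to an end step", pm$name))
    if (ok_head && ok_tail) {
      walked <- tryCatch(nrow(path_table(g, pid)), error = function(e) -1L)
      if (walked != pm$step_count) {
        bad <- c(bad, sprintf("path '%s': walk length %d != recorded step count %d",
                              pm$name, walked, pm$step_count))
      }
    }
  }
  node_steps <- sum(vapply(ls(g$nodes, sorted = FALSE),
                           function(k) length(get(k, envir = g$nodes)$steps), integer(1)))
  if (node_steps != total_steps) {
    bad <- c(bad, sprintf("step accounting: %d steps on nodes vs %d across paths",
                          node_steps, total_steps))
  }
  bad
}

#' Storage accounting for the relativistic encoding
#'
#' Reports, per node, how many integers the adjacency and step storage use.
#' Each edge record costs two integers (a delta plus a packed strand pair)
#' and each step at most eight, mirroring the asymptotic storage contract of
#' the node-centric encoding.
#'
#' @param g A `vg_graph`.
#' @return Data frame with columns `node`, `n_edge_records`, `edge_ints`,
#'   `n_steps`, `step_ints`.
#' @export
vg_storage_accounting <- function(g) {
  ids <- vg_node_ids(g)
  do.call(rbind, lapply(ids, function(id) {
    nd <- get_node(g, id)
    data.frame(node = id,
               n_edge_records = length(nd$edges),
               edge_ints = 2L * length(nd$edges),
               n_steps = length(nd$steps),
               step_ints = 8L * length(nd$steps))
  }))
}

# deep copy (graphs are environments)
vg_clone <- function(g) {
  ng <- vg_new()
  for (k in ls(g$nodes, sorted = FALSE)) assign(k, get(k, envir = g$nodes), envir = ng$nodes)
  for (k in ls(g$paths, sorted = FALSE)) assign(k, get(k, envir = g$paths), envir = ng$paths)
  for (k in ls(g$path_names, sorted = FALSE)) assign(k, get(k, envir = g$path_names), envir = ng$path_names)
  for (k in ls(g$seg_names, sorted = FALSE)) assign(k, get(k, envir = g$seg_names), envir = ng$seg_names)
  ng$path_order <- g$path_order
  ng$next_path_id <- g$next_path_id
  ng$max_id <- g$max_id
  ng$min_id <- g$min_id
  ng
}
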