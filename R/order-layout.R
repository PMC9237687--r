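# Node ordering and layout. Two families: a deterministic topological sort
# over the bidirected adjacency, and the path-guided stochastic gradient
# descent (PG-SGD) that learns 1D positions or 2D coordinates matching
# nucleotide distances along the embedded paths. The SGD objective is
#   sum_terms w * (d - dist)^2,   w = d^-2,
# with d the bp distance between two sampled steps of one path, dist the
# current layout distance. The learning rate decays geometrically from
# eta_max to eps; the serial implementation is deterministic under a seed.

#' Topological node order over the bidirected adjacency
#'
#' A Kahn-style sort in handle space: a strand is "ready" when every edge on
#' its incoming side comes from an already-placed node. Seeds prefer strands
#' with no incoming edges, lowest id first; when only cycles remain, the
#' lowest-id unplaced node is forced (back edges are permitted). On
#' DAG-like graphs every forward edge respects the resulting order.
#'
#' @param g A `vg_graph`.
#' @return Integer permutation of the node ids.
#' @export
topological_order <- function(g) {
  ids <- vg_node_ids(g)
  placed <- new.env(parent = emptyenv())
  is_placed <- function(id) exists(nkey(id), envir = placed, inherits = FALSE)
  ready <- function(h) {  # all left-side edges come from placed nodes
    ins <- out_edges(g, handle_flip(h))
    all(vapply(ins, function(x) x$id == h$id || is_placed(x$id), logical(1)))
  }
  order <- integer(0)
  remaining <- ids
  while (length(remaining)) {
    seed_h <- NULL
    for (id in remaining) {
      if (ready(vg_handle(id, FALSE))) { seed_h <- vg_handle(id, FALSE); break }
      if (ready(vg_handle(id, TRUE)))  { seed_h <- vg_handle(id, TRUE);  break }
    }
    if (is.null(seed_h)) seed_h <- vg_handle(remaining[1], FALSE)  # cycle: force
    queue <- list(seed_h)
    while (length(queue)) {
      h <- queue[[1]]; queue <- queue[-1]
      if (is_placed(h$id)) next
      assign(nkey(h$id), TRUE, envir = placed)
      order <- c(order, h$id)
      outs <- out_edges(g, h)
      if (length(outs)) {
        outs <- outs[order(vapply(outs, handle_id, integer(1)))]
        for (o in outs) {
          if (!is_placed(o$id) && ready(o)) queue[[length(queue) + 1L]] <- o
        }
      }
    }
    remaining <- setdiff(remaining, order)
  }
  order
}

# per-path step tables plus a flat index of all steps, shared by the SGD
# routines and the stress estimator
sgd_prepare <- function(g) {
  pids <- g$path_order
  tables <- lapply(pids, function(pid) path_table(g, pid))
  keep <- vapply(tables, nrow, integer(1)) > 0L
  tables <- tables[keep]
  if (length(tables) == 0L) {
    stop("graph has no non-empty path: no distance signal for PG-SGD")
  }
  steps_per_path <- vapply(tables, nrow, integer(1))
  list(tables = tables,
       steps_per_path = steps_per_path,
       total_steps = sum(steps_per_path),
       path_of_step = rep(seq_along(tables), steps_per_path),
       rank_of_step = unlist(lapply(steps_per_path, seq_len)))
}

# sample term endpoints: a uniformly chosen step and a second step of the
# same path at a Zipf-distributed rank offset (exponent `zipf_theta`)
sample_terms <- function(prep, n, zipf_theta = 0.99) {
  i <- sample.int(prep$total_steps, n, replace = TRUE)
  p <- prep$path_of_step[i]
  r1 <- prep$rank_of_step[i]
  K <- prep$steps_per_path[p]
  r2 <- integer(n)
  for (t in seq_len(n)) {
    k <- K[t]
    if (k < 2L) { r2[t] <- r1[t]; next }
    off <- sample.int(k - 1L, 1L, prob = (seq_len(k - 1L))^(-zipf_theta))
    up <- r1[t] + off <= k
    down <- r1[t] - off >= 1L
    r2[t] <- if (up && down) {
      if (runif(1) < 0.5) r1[t] + off else r1[t] - off
    } else if (up) {
      r1[t] + off
    } else if (down) {
      r1[t] - off
    } else {
      # offset exceeds both directions: take the farther end of the path
      if (k - r1[t] >= r1[t] - 1L) k else 1L
    }
  }
  keep <- r2 != r1
  list(path = p[keep], r1 = r1[keep], r2 = r2[keep])
}

step_midpoint <- function(tb, r) tb$start[r] + tb$len[r] / 2

# geometric learning-rate schedule from eta_max down to eps
eta_schedule <- function(eta_max, eps, iterations) {
  if (iterations <= 1L) return(eta_max)
  lambda <- log(eta_max / eps) / (iterations - 1L)
  eta_max * exp(-lambda * (seq_len(iterations) - 1L))
}

layout_new <- function(dims, coords, schedule, seed, extra = list()) {
  structure(c(list(dims = dims, coords = coords, schedule = schedule,
                   seed = seed), extra),
            class = "vg_layout")
}

#' @export
print.vg_layout <- function(x, ...) {
  cat(sprintf("<%dD PG-SGD layout of %d node%s; stress %.4g (from %.4g)>\n",
              x$dims,
              if (x$dims == 1L) length(x$coords) else nrow(x$coords) / 2L,
              "s", x$stress_final, x$stress_initial))
  invisible(x)
}

#' Path-guided SGD in one dimension
#'
#' Learns a 1D position per node (its midpoint) such that layout distances
#' match nucleotide distances between step midpoints along the embedded
#' paths. Per sampled term the two node positions are moved toward/away by
#' the correction `(|x_a - x_b| - d) / 2`, scaled by
#' `mu = min(1, eta_t * w)`; `eta_t` decays geometrically from `eta_max`
#' (default: the squared maximum sampled distance) to `eps`. Execution stops
#' after `iterations` rounds or when the largest per-term displacement of a
#' round falls below `eps`.
#'
#' @param g A `vg_graph` with at least one non-empty path.
#' @param iterations Number of rounds.
#' @param eta_max Initial learning rate; default `max(d)^2` over a sampled
#'   term set, which makes the first corrections saturate (`mu = 1`).
#' @param eps Final learning rate and displacement threshold.
#' @param seed Integer seed; the serial implementation is fully
#'   deterministic under it.
#' @param terms_per_iteration Sampled terms per round (default
#'   `20 * total step count`; dense sampling keeps rare chain-fold local
#'   minima from surviving the schedule).
#' @param zipf_theta Exponent of the Zipf rank-offset distribution used to
#'   mix short- and long-range terms.
#' @return A `vg_layout` with fields `coords` (named by node id),
#'   `coords_initial`, `stress_initial`, `stress_final`, `schedule`, `seed`.
#' @export
pg_sgd_1d <- function(g, iterations = 30, eta_max = NULL, eps = 0.01,
                      seed = 1, terms_per_iteration = NULL, zipf_theta = 0.99) {
  prep <- sgd_prepare(g)
  ids <- vg_node_ids(g)
  lens <- vapply(ids, function(id) nchar(vg_sequence(g, id)), numeric(1))
  x <- cumsum(lens) - lens / 2  # midpoints in current id order
  names(x) <- nkey(ids)
  x0 <- x
  if (is.null(terms_per_iteration)) {
    terms_per_iteration <- max(100L, 20L * prep$total_steps)
  }
  with_seed(seed, {
    if (is.null(eta_max)) {
      probe <- sample_terms(prep, min(1000L, terms_per_iteration), zipf_theta)
      dmax <- 0
      for (t in seq_along(probe$path)) {
        tb <- prep$tables[[probe$path[t]]]
        dmax <- max(dmax, abs(step_midpoint(tb, probe$r1[t]) -
                                step_midpoint(tb, probe$r2[t])))
      }
      eta_max <- max(dmax^2, 1)
    }
    etas <- eta_schedule(eta_max, eps, iterations)
    for (it in seq_len(iterations)) {
      terms <- sample_terms(prep, terms_per_iteration, zipf_theta)
      max_move <- 0
      for (t in seq_along(terms$path)) {
        tb <- prep$tables[[terms$path[t]]]
        a <- nkey(tb$node[terms$r1[t]]); b <- nkey(tb$node[terms$r2[t]])
        if (a == b) next
        d <- abs(step_midpoint(tb, terms$r1[t]) - step_midpoint(tb, terms$r2[t]))
        if (d <= 0) next
        w <- d^-2
        mu <- min(1, etas[it] * w)
        dx <- x[[a]] - x[[b]]
        dist <- abs(dx)
        if (dist < 1e-9) { dx <- if (a < b) -1e-9 else 1e-9; dist <- 1e-9 }
        move <- mu * (dist - d) / 2 * (dx / dist)
        x[[a]] <- x[[a]] - move
        x[[b]] <- x[[b]] + move
        max_move <- max(max_move, abs(move))
      }
      if (max_move < eps) break
    }
  })
  lay <- layout_new(1L, x, list(eta_max = eta_max, eps = eps,
                                iterations = iterations), seed,
                    extra = list(coords_initial = x0))
  lay$stress_initial <- layout_stress(g, replace_coords(lay, x0), seed = seed + 1L)
  lay$stress_final <- layout_stress(g, lay, seed = seed + 1L)
  lay
}

replace_coords <- function(layout, coords) {
  layout$coords <- coords
  layout
}

#' Node order induced by a 1D layout
#'
#' Ranks the learned coordinates; ties break by node id.
#'
#' @param layout A 1D `vg_layout`.
#' @return Integer vector of node ids in layout order.
#' @export
layout_order <- function(layout) {
  stopifnot(layout$dims == 1L)
  ids <- as.integer(names(layout$coords))
  ids[order(layout$coords, ids)]
}

#' Path-guided SGD in two dimensions
#'
#' As [pg_sgd_1d()], but each node is laid out by its two endpoints (rows
#' `"<id>.0"` and `"<id>.1"` of the coordinate matrix, for the start/end of
#' the forward strand), with Euclidean distance replacing `|dx|`. Sampled
#' terms connect random endpoints of two steps of one path; a zero rank
#' offset pairs the two endpoints of a single step at the node's own length,
#' which keeps nodes extended. Initial coordinates are the 1D prefix-sum
#' offsets of the current id order plus seeded uniform noise in y.
#'
#' @inheritParams pg_sgd_1d
#' @return A `vg_layout` with `coords` a `2|N| x 2` matrix.
#' @export
pg_sgd_2d <- function(g, iterations = 30, eta_max = NULL, eps = 0.01,
                      seed = 1, terms_per_iteration = NULL, zipf_theta = 0.99) {
  prep <- sgd_prepare(g)
  ids <- vg_node_ids(g)
  lens <- vapply(ids, function(id) nchar(vg_sequence(g, id)), numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  if (is.null(terms_per_iteration)) {
    terms_per_iteration <- max(200L, 20L * prep$total_steps)
  }
  coords <- NULL
  with_seed(seed, {
    ynoise <- runif(2L * length(ids), 0, max(mean(lens), 1))
    coords <- matrix(0, nrow = 2L * length(ids), ncol = 2L,
                     dimnames = list(paste0(rep(ids, each = 2L), c(".0", ".1")),
                                     c("x", "y")))
    coords[seq(1L, 2L * length(ids), by = 2L), 1] <- starts
    coords[seq(2L, 2L * length(ids), by = 2L), 1] <- ends
    coords[, 2] <- ynoise
  })
  coords0 <- coords
  row_of <- function(node, end) paste0(node, ".", end)
  with_seed(seed + 1L, {
    if (is.null(eta_max)) {
      plens <- vapply(prep$tables, function(tb) sum(tb$len), numeric(1))
      eta_max <- max(max(plens)^2, 1)
    }
    etas <- eta_schedule(eta_max, eps, iterations)
    for (it in seq_len(iterations)) {
      i <- sample.int(prep$total_steps, terms_per_iteration, replace = TRUE)
      p <- prep$path_of_step[i]
      r1 <- prep$rank_of_step[i]
      max_move <- 0
      for (t in seq_len(terms_per_iteration)) {
        tb <- prep$tables[[p[t]]]
        k <- nrow(tb)
        off <- if (k < 2L) 0L else {
          sample.int(k, 1L, prob = (seq_len(k))^(-zipf_theta)) - 1L
        }
        if (off == 0L) {
          # one step's own two endpoints, at the node's length apart
          r2 <- r1[t]
          e1 <- 0L; e2 <- 1L
          d <- tb$len[r2]
        } else {
          up <- r1[t] + off <= k
          down <- r1[t] - off >= 1L
          r2 <- if (up && down) {
            if (runif(1) < 0.5) r1[t] + off else r1[t] - off
          } else if (up) r1[t] + off else if (down) r1[t] - off else {
            if (k - r1[t] >= r1[t] - 1L) k else 1L
          }
          e1 <- sample(0:1, 1L); e2 <- sample(0:1, 1L)
          # path offset of a step endpoint: forward steps put endpoint 0 at
          # the step start; reverse steps put it at the step end
          off1 <- tb$start[r1[t]] + if (tb$rev[r1[t]]) (1L - e1) * tb$len[r1[t]] else e1 * tb$len[r1[t]]
          off2 <- tb$start[r2] + if (tb$rev[r2]) (1L - e2) * tb$len[r2] else e2 * tb$len[r2]
          d <- abs(off1 - off2)
        }
        if (d <= 0) next
        ra <- row_of(tb$node[r1[t]], e1); rb <- row_of(tb$node[r2], e2)
        if (ra == rb) next
        w <- d^-2
        mu <- min(1, etas[it] * w)
        dv <- coords[ra, ] - coords[rb, ]
        dist <- sqrt(sum(dv^2))
        if (dist < 1e-9) { dv <- c(1e-9, 0); dist <- 1e-9 }
        move <- (mu * (dist - d) / 2) * (dv / dist)
        coords[ra, ] <- coords[ra, ] - move
        coords[rb, ] <- coords[rb, ] + move
        max_move <- max(max_move, sqrt(sum(move^2)))
      }
      if (max_move < eps) break
    }
  })
  lay <- layout_new(2L, coords, list(eta_max = eta_max, eps = eps,
                                     iterations = iterations), seed,
                    extra = list(coords_initial = coords0))
  lay$stress_initial <- layout_stress(g, replace_coords(lay, coords0), seed = seed + 2L)
  lay$stress_final <- layout_stress(g, lay, seed = seed + 2L)
  lay
}

#' Monte-Carlo stress of a layout
#'
#' Estimates the PG-SGD objective `mean over terms of w * (d - dist)^2`
#' by sampling terms exactly as the optimizer does. Zero for a perfect
#' 1D placement of a chain at its true path offsets.
#'
#' @param g A `vg_graph`.
#' @param layout A `vg_layout` (1D or 2D).
#' @param n_terms Number of sampled terms.
#' @param seed Integer seed.
#' @return Non-negative scalar.
#' @export
layout_stress <- function(g, layout, n_terms = 1000, seed = 1) {
  prep <- sgd_prepare(g)
  with_seed(seed, {
    total <- 0
    used <- 0L
    terms <- sample_terms(prep, n_terms)
    for (t in seq_along(terms$path)) {
      tb <- prep$tables[[terms$path[t]]]
      d <- abs(step_midpoint(tb, terms$r1[t]) - step_midpoint(tb, terms$r2[t]))
      if (d <= 0) next
      a <- tb$node[terms$r1[t]]; b <- tb$node[terms$r2[t]]
      if (a == b) next
      dist <- if (layout$dims == 1L) {
        abs(layout$coords[[nkey(a)]] - layout$coords[[nkey(b)]])
      } else {
        # node midpoints from endpoint rows
        pa <- (layout$coords[paste0(a, ".0"), ] + layout$coords[paste0(a, ".1"), ]) / 2
        pb <- (layout$coords[paste0(b, ".0"), ] + layout$coords[paste0(b, ".1"), ]) / 2
        sqrt(sum((pa - pb)^2))
      }
      total <- total + d^-2 * (d - dist)^2
      used <- used + 1L
    }
    if (used == 0L) 0 else total / used
  })
}

#' Write a layout as TSV
#'
#' 1D: columns `node_id`, `x`. 2D: `node_id`, `x`, `y`, `x_end`, `y_end`.
#'
#' @param layout A `vg_layout`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_layout_tsv <- function(layout, file) {
  if (layout$dims == 1L) {
    df <- data.frame(node_id = as.integer(names(layout$coords)),
                     x = as.numeric(layout$coords))
  } else {
    rn <- rownames(layout$coords)
    start_rows <- grepl("\\.0$", rn)
    ids <- as.integer(sub("\\.0$", "", rn[start_rows]))
    df <- data.frame(node_id = ids,
                     x = layout$coords[start_rows, 1],
                     y = layout$coords[start_rows, 2],
                     x_end = layout$coords[!start_rows, 1],
                     y_end = layout$coords[!start_rows, 2])
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
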