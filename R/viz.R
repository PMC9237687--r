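# 1D binned visualization (paths x pangenome position) with four color
# modalities — path name, path position, strand, node depth — plus SVG
# rendering of 2D layouts. The pangenome axis is the node order by id;
# each path is a row, each bin a column, and empty cells stay white.

#' Bin a graph onto the pangenome axis
#'
#' Nodes are laid along the horizontal axis in current id order (offsets by
#' prefix sum); the axis is divided into `width_bins` bins of
#' `ceiling(total_len / width_bins)` bp (the last bin may be partial). For
#' each path and bin the covered bases, mean along-path position,
#' reverse-strand base fraction and mean node depth are aggregated. Depth
#' here is the path's own step count on the node (self-coverage); set
#' `all_paths_depth = TRUE` for all-paths node depth.
#'
#' @param g A `vg_graph`.
#' @param width_bins Number of bins (>= 1).
#' @param all_paths_depth Use all-paths node depth instead of per-path depth.
#' @return A list of class `vg_bins`: `cells` (data frame `path`, `bin`,
#'   `covered_bp`, `mean_path_pos`, `rev_fraction`, `mean_depth`),
#'   `bin_size`, `n_bins`, `paths`, `path_lens`, `total_len`, `offsets`.
#' @export
bin_matrix <- function(g, width_bins, all_paths_depth = FALSE) {
  stopifnot(width_bins >= 1L)
  ids <- vg_node_ids(g)
  lens <- vapply(ids, function(id) nchar(vg_sequence(g, id)), integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  names(offs) <- nkey(ids)
  total <- sum(lens)
  bs <- max(1L, as.integer(ceiling(total / width_bins)))
  n_bins <- max(1L, as.integer(ceiling(total / bs)))
  pnames <- vg_paths(g)
  cells <- list()
  plens <- integer(length(pnames))
  for (pi in seq_along(g$path_order)) {
    tb <- path_table(g, g$path_order[pi])
    plens[pi] <- sum(tb$len)
    if (nrow(tb) == 0L) next
    # per-bp vectors along the path
    n_bp <- sum(tb$len)
    pan_pos <- integer(n_bp); path_pos <- integer(n_bp)
    revv <- logical(n_bp); depthv <- integer(n_bp)
    at <- 0L
    for (i in seq_len(nrow(tb))) {
      len <- tb$len[i]
      node_bp <- seq_len(len) - 1L              # base index in forward seq
      idx <- at + seq_len(len)
      pan_pos[idx] <- offs[[nkey(tb$node[i])]] + node_bp
      path_pos[idx] <- tb$start[i] +
        if (tb$rev[i]) (len - 1L - node_bp) else node_bp
      revv[idx] <- tb$rev[i]
      depthv[idx] <- if (all_paths_depth) node_depth(g, tb$node[i]) else {
        sum(tb$node == tb$node[i])
      }
      at <- at + len
    }
    bin <- pan_pos %/% bs
    agg <- function(v, f) tapply(v, bin, f)
    cb <- agg(pan_pos, length)
    cells[[length(cells) + 1L]] <- data.frame(
      path = pnames[pi],
      bin = as.integer(names(cb)),
      covered_bp = as.integer(cb),
      mean_path_pos = as.numeric(agg(path_pos, mean)),
      rev_fraction = as.numeric(agg(revv, mean)),
      mean_depth = as.numeric(agg(depthv, mean)),
      row.names = NULL)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else {
    data.frame(path = character(0), bin = integer(0), covered_bp = integer(0),
               mean_path_pos = numeric(0), rev_fraction = numeric(0),
               mean_depth = numeric(0))
  }
  structure(list(cells = cells, bin_size = bs, n_bins = n_bins,
                 paths = pnames, path_lens = plens, total_len = total,
                 offsets = offs),
            class = "vg_bins")
}

#' Depth palette
#'
#' The banded node-depth palette: white for no depth, then gray, red and
#' yellow for depths 1, 2 and >= 3. Band boundaries sit at 1.5 and 2.5 so
#' fractional bin means fall into the nearest class.
#'
#' @param mean_depth Non-negative depth value(s).
#' @return Integer matrix with columns `r`, `g`, `b` (0-255), one row per input.
#' @examples
#' depth_color(c(0, 1, 2, 3, 5))
#' @export
depth_color <- function(mean_depth) {
  stopifnot(all(mean_depth >= 0))
  pal <- rbind(white = c(255L, 255L, 255L), gray = c(128L, 128L, 128L),
               red = c(255L, 0L, 0L), yellow = c(255L, 255L, 0L))
  cls <- ifelse(mean_depth <= 0, 1L,
                ifelse(mean_depth <= 1.5, 2L,
                       ifelse(mean_depth <= 2.5, 3L, 4L)))
  m <- pal[cls, , drop = FALSE]
  colnames(m) <- c("r", "g", "b")
  m
}

# deterministic byte-wise digest of a path name -> hue in [0, 1)
name_hue <- function(name) {
  bytes <- utf8ToInt(name)
  acc <- 0
  for (b in bytes) acc <- (acc * 131 + b) %% 360
  acc / 360
}

name_color <- function(name) {
  rgb <- grDevices::col2rgb(grDevices::hsv(name_hue(name), 0.65, 0.85))
  as.integer(rgb[, 1])
}

#' Render the 1D binned visualization
#'
#' One pixel row per path (declaration order), one column per bin; empty
#' cells are white. Modalities: `"name"` colors each path by a
#' deterministic digest of its name; `"position"` ramps from light gray
#' (path start) to dark gray (path end) by mean along-path position;
#' `"strand"` paints cells black (forward) or red (majority
#' reverse-complement); `"depth"` applies [depth_color()]. A link track
#' lists edges whose endpoint bins are not adjacent.
#'
#' @param g A `vg_graph`.
#' @param width_bins Number of bins.
#' @param modality One of `"name"`, `"position"`, `"strand"`, `"depth"`.
#' @param all_paths_depth Passed to [bin_matrix()].
#' @return A list of class `vg_viz1d`: `pixels` (array rows x bins x 3),
#'   `row_labels`, `links` (data frame `from_bin`, `to_bin`), `bins`.
#' @export
render_1d <- function(g, width_bins,
                      modality = c("name", "position", "strand", "depth"),
                      all_paths_depth = FALSE) {
  modality <- match.arg(modality)
  bm <- bin_matrix(g, width_bins, all_paths_depth = all_paths_depth)
  nr <- length(bm$paths)
  px <- array(255L, dim = c(max(nr, 1L), bm$n_bins, 3L))
  for (i in seq_len(nrow(bm$cells))) {
    cell <- bm$cells[i, ]
    row <- match(cell$path, bm$paths)
    col <- cell$bin + 1L
    rgbv <- switch(modality,
      name = name_color(cell$path),
      position = {
        plen <- bm$path_lens[row]
        frac <- if (plen > 0L) cell$mean_path_pos / plen else 0
        gval <- as.integer(round(220 - frac * 190))  # light -> dark
        c(gval, gval, gval)
      },
      strand = if (cell$rev_fraction > 0.5) c(255L, 0L, 0L) else c(0L, 0L, 0L),
      depth = as.integer(depth_color(cell$mean_depth)[1, ]))
    px[row, col, ] <- rgbv
  }
  # link track: edges whose endpoint bins are non-adjacent
  ids <- vg_node_ids(g)
  lens <- vapply(ids, function(id) nchar(vg_sequence(g, id)), integer(1))
  names(lens) <- nkey(ids)
  ed <- vg_edges(g)
  links <- list()
  for (i in seq_len(nrow(ed))) {
    # attachment points: 3' end of the from strand, 5' end of the to strand
    f <- vg_handle(ed$from_id[i], ed$from_rev[i])
    t <- vg_handle(ed$to_id[i], ed$to_rev[i])
    fpos <- bm$offsets[[nkey(f$id)]] + if (f$rev) 0L else lens[[nkey(f$id)]] - 1L
    tpos <- bm$offsets[[nkey(t$id)]] + if (t$rev) lens[[nkey(t$id)]] - 1L else 0L
    fb <- fpos %/% bm$bin_size; tb <- tpos %/% bm$bin_size
    if (abs(fb - tb) > 1L) {
      links[[length(links) + 1L]] <- data.frame(from_bin = min(fb, tb),
                                                to_bin = max(fb, tb))
    }
  }
  links <- if (length(links)) unique(do.call(rbind, links)) else {
    data.frame(from_bin = integer(0), to_bin = integer(0))
  }
  structure(list(pixels = px, row_labels = bm$paths, links = links,
                 bins = bm, modality = modality),
            class = "vg_viz1d")
}

#' @export
print.vg_viz1d <- function(x, ...) {
  cat(sprintf("<1D viz: %d path rows x %d bins, modality '%s', %d long-range links>\n",
              length(x$row_labels), dim(x$pixels)[2], x$modality, nrow(x$links)))
  invisible(x)
}

#' Write a pixel array as a PPM (P3) image
#'
#' Plain-text portable pixmap; any raster viewer or converter reads it.
#' If the `png` package is installed, [write_png()] writes PNG directly.
#'
#' @param pixels `rows x cols x 3` integer array (0-255).
#' @param file Output path.
#' @param scale Integer pixel-duplication factor for visibility.
#' @return `file`, invisibly.
#' @export
write_ppm <- function(pixels, file, scale = 1L) {
  d <- dim(pixels)
  rows <- rep(seq_len(d[1]), each = scale)
  cols <- rep(seq_len(d[2]), each = scale)
  body <- character(length(rows))
  for (ri in seq_along(rows)) {
    m <- pixels[rows[ri], cols, , drop = FALSE]
    body[ri] <- paste(t(m[1, , ]), collapse = " ")
  }
  writeLines(c("P3", paste(length(cols), length(rows)), "255", body), file)
  invisible(file)
}

#' @rdname write_ppm
#' @export
write_png <- function(pixels, file, scale = 1L) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is not installed; use write_ppm()")
  }
  d <- dim(pixels)
  rows <- rep(seq_len(d[1]), each = scale)
  cols <- rep(seq_len(d[2]), each = scale)
  img <- array(0, dim = c(length(rows), length(cols), 3L))
  for (k in 1:3) img[, , k] <- pixels[rows, cols, k] / 255
  png::writePNG(img, file)
  invisible(file)
}

#' Render a 2D layout as SVG
#'
#' One line segment per node (between its two endpoint coordinates) and one
#' thin line per edge (connecting the corresponding node ends), inside a
#' viewBox fitted to the coordinate bounds with a 5% margin.
#'
#' @param g A `vg_graph`.
#' @param layout A 2D `vg_layout` covering all nodes.
#' @param file Optional output path.
#' @return SVG document as a character scalar (invisibly when `file` given).
#' @export
draw_svg <- function(g, layout, file = NULL) {
  stopifnot(layout$dims == 2L)
  ids <- vg_node_ids(g)
  need <- paste0(rep(ids, each = 2L), c(".0", ".1"))
  missing <- setdiff(need, rownames(layout$coords))
  if (length(missing)) {
    stop("layout is missing coordinates for: ",
         paste(unique(sub("\\..$", "", missing)), collapse = ", "))
  }
  xs <- layout$coords[need, 1]; ys <- layout$coords[need, 2]
  rngx <- range(xs); rngy <- range(ys)
  mx <- max(diff(rngx), 1) * 0.05; my <- max(diff(rngy), 1) * 0.05
  vb <- sprintf("%g %g %g %g", rngx[1] - mx, rngy[1] - my,
                diff(rngx) + 2 * mx, diff(rngy) + 2 * my)
  seg <- function(x1, y1, x2, y2, cls, wd) {
    sprintf('<line class="%s" x1="%g" y1="%g" x2="%g" y2="%g" stroke="%s" stroke-width="%g"/>',
            cls, x1, y1, x2, y2, if (cls == "node") "black" else "#888888", wd)
  }
  wd_node <- max(diff(rngx), diff(rngy), 1) / 400
  lines <- character(0)
  end_coord <- function(h, side) {
    # the point where an edge attaches: 3' end of a "from" strand,
    # 5' end of a "to" strand
    e <- if (side == "from") (if (h$rev) 0L else 1L) else (if (h$rev) 1L else 0L)
    layout$coords[paste0(h$id, ".", e), ]
  }
  ed <- vg_edges(g)
  for (i in seq_len(nrow(ed))) {
    p1 <- end_coord(vg_handle(ed$from_id[i], ed$from_rev[i]), "from")
    p2 <- end_coord(vg_handle(ed$to_id[i], ed$to_rev[i]), "to")
    lines <- c(lines, seg(p1[1], p1[2], p2[1], p2[2], "edge", wd_node / 2))
  }
  for (id in ids) {
    a <- layout$coords[paste0(id, ".0"), ]
    b <- layout$coords[paste0(id, ".1"), ]
    lines <- c(lines, seg(a[1], a[2], b[1], b[2], "node", wd_node))
  }
  doc <- paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s">', vb),
                 lines, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
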