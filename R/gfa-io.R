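# GFAv1 reading and writing, PanSN path-name parsing, and the native
# serialized graph format. Conversion is lossless: every S/L/P record of the
# input is represented, and emission uses a fixed canonical order (header,
# S by ascending id, L by canonical endpoints, P in creation order) so that
# write(parse(write(g))) is byte-identical to write(g).

#' Parse a GFAv1 graph
#'
#' Accepts `H`, `S`, `L` and `P` lines. Segment names that are not positive
#' integers are mapped to fresh integer ids in first-seen order; the original
#' names are retained in a translation table and restored on emission.
#' Only blunt-ended overlaps (`*` or `0M`) are accepted: pangenome graphs do
#' not use overlap CIGARs, and anything richer is rejected loudly rather
#' than silently dropped. GFAv2 and rGFA markers are rejected.
#'
#' @param x Path to a GFA file, or a character vector of GFA lines.
#' @return A `vg_graph`.
#' @export
read_gfa <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(lines)]
  g <- vg_new()
  name_map <- new.env(parent = emptyenv())  # GFA segment name -> node id
  any_named <- FALSE

  resolve_seg <- function(name) {
    if (exists(name, envir = name_map, inherits = FALSE)) {
      return(get(name, envir = name_map))
    }
    stop("GFA references unknown segment '", name, "'")
  }

  recs <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(recs, `[`, character(1), 1L)
  if (any(types %in% c("E", "G", "F", "O", "U"))) {
    stop("GFAv2 record types found; only GFAv1 is supported")
  }
  seg_recs <- recs[types == "S"]
  seg_names <- vapply(seg_recs, function(f) {
    if (length(f) < 3L) stop("malformed S line")
    if (any(startsWith(f[-(1:3)], "SN:Z:"))) {
      stop("rGFA SN tags found; rGFA is not supported")
    }
    f[2]
  }, character(1))
  if (anyDuplicated(seg_names)) {
    stop("duplicate segment '", seg_names[duplicated(seg_names)][1], "'")
  }
  # all-integer names are used as ids directly; otherwise every name is
  # mapped to a fresh id in first-seen order, original names retained
  use_table <- any_named <- length(seg_names) > 0L &&
    !all(grepl("^[0-9]+$", seg_names))
  for (f in recs) {
    if (f[1] == "H" && length(f) > 1L) {
      vn <- grep("^VN:Z:", f[-1], value = TRUE)
      if (length(vn) && !startsWith(sub("^VN:Z:", "", vn[1]), "1")) {
        stop("unsupported GFA version: ", sub("^VN:Z:", "", vn[1]))
      }
    }
    if (f[1] == "S") {
      name <- f[2]
      if (use_table) {
        id <- g$max_id + 1L
        vg_add_node(g, f[3], id)
        assign(nkey(id), name, envir = g$seg_names)
      } else {
        id <- as.integer(name)
        vg_add_node(g, f[3], id)
      }
      assign(name, id, envir = name_map)
    }
  }
  for (f in recs) {
    if (f[1] == "L") {
      if (length(f) < 6L) stop("malformed L line")
      if (!(f[6] %in% c("*", "0M"))) {
        stop("unsupported L overlap '", f[6], "': only * or 0M are accepted")
      }
      a <- vg_handle(resolve_seg(f[2]), f[3] == "-")
      b <- vg_handle(resolve_seg(f[4]), f[5] == "-")
      vg_add_edge(g, a, b)
    }
  }
  for (f in recs) {
    if (f[1] == "P") {
      if (length(f) < 3L) stop("malformed P line")
      pid <- vg_add_path(g, f[2])
      if (f[3] != "*" && nzchar(f[3])) {
        steps <- strsplit(f[3], ",", fixed = TRUE)[[1]]
        for (s in steps) {
          sn <- sub("[+-]$", "", s)
          rev <- endsWith(s, "-")
          vg_append_step(g, pid, vg_handle(resolve_seg(sn), rev))
        }
      }
      if (length(f) >= 4L && !(f[4] %in% c("*", "")) &&
          any(!strsplit(f[4], ",", fixed = TRUE)[[1]] %in% c("*", "0M"))) {
        stop("unsupported P overlaps '", f[4], "'")
      }
    }
  }
  g
}

seg_display_name <- function(g, id) {
  k <- nkey(id)
  if (exists(k, envir = g$seg_names, inherits = FALSE)) {
    get(k, envir = g$seg_names)
  } else {
    k
  }
}

#' Emit a graph as GFAv1 text
#'
#' Canonical emission order: one `H` line, `S` lines by ascending node id,
#' `L` lines sorted by canonical endpoints, `P` lines in path-creation
#' order. Original segment names from the translation table are restored.
#'
#' @param g A `vg_graph`.
#' @param file Optional path to write to.
#' @return The GFA lines as a character vector (invisibly when `file` is given).
#' @export
write_gfa <- function(g, file = NULL) {
  out <- "H\tVN:Z:1.0"
  for (id in vg_node_ids(g)) {
    out <- c(out, paste("S", seg_display_name(g, id), vg_sequence(g, id), sep = "\t"))
  }
  ed <- vg_edges(g)
  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      out <- c(out, paste("L",
                          seg_display_name(g, ed$from_id[i]),
                          if (ed$from_rev[i]) "-" else "+",
                          seg_display_name(g, ed$to_id[i]),
                          if (ed$to_rev[i]) "-" else "+",
                          "0M", sep = "\t"))
    }
  }
  for (pid in g$path_order) {
    pm <- get_path_meta(g, pid)
    tb <- path_table(g, pid)
    stepstr <- if (nrow(tb) == 0L) "*" else {
      paste(paste0(vapply(tb$node, function(n) seg_display_name(g, n), character(1)),
                   ifelse(tb$rev, "-", "+")), collapse = ",")
    }
    out <- c(out, paste("P", pm$name, stepstr, "*", sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse a PanSN sequence name
#'
#' PanSN embeds biosample structure in sequence names as
#' `sample#haplotype#contig`. Names with a delimiter count other than two
#' are not guessed at: they fall back to `NULL` (treat the whole name as a
#' bare contig).
#'
#' @param name Sequence name.
#' @param delim Delimiter, default `"#"`.
#' @return A list with `sample`, `haplotype`, `contig`, `raw`, or `NULL`
#'   when the name is not strictly PanSN.
#' @examples
#' parse_pansn("HG002#1#chr6")
#' parse_pansn("chr6")  # NULL
#' @export
parse_pansn <- function(name, delim = "#") {
  parts <- strsplit(name, delim, fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts))) return(NULL)
  list(sample = parts[1], haplotype = parts[2], contig = parts[3], raw = name)
}

NATIVE_MAGIC <- charToRaw("VGRN")
NATIVE_VERSION <- as.raw(1L)

#' Save / load a graph in the native serialized format
#'
#' A compact on-disk form carrying a magic string and a version byte ahead
#' of the serialized node and path tables (including the segment-name
#' translation table). `load_native(save_native(g))` reproduces the graph
#' exactly, path names and step orientations included.
#'
#' @param g A `vg_graph`.
#' @param file Path to write to / read from.
#' @return `load_native()` returns a `vg_graph`; `save_native()` returns
#'   `file` invisibly.
#' @export
save_native <- function(g, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(NATIVE_MAGIC, con)
  writeBin(NATIVE_VERSION, con)
  snapshot <- list(
    nodes = mget(ls(g$nodes, sorted = FALSE), envir = g$nodes),
    paths = mget(ls(g$paths, sorted = FALSE), envir = g$paths),
    path_names = mget(ls(g$path_names, sorted = FALSE), envir = g$path_names),
    seg_names = mget(ls(g$seg_names, sorted = FALSE), envir = g$seg_names),
    path_order = g$path_order,
    next_path_id = g$next_path_id,
    max_id = g$max_id,
    min_id = g$min_id)
  serialize(snapshot, con)
  invisible(file)
}

#' @rdname save_native
#' @export
load_native <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, NATIVE_MAGIC)) {
    stop("not a native graph file (bad magic)")
  }
  version <- readBin(con, "raw", n = 1L)
  if (length(version) < 1L || !identical(version, NATIVE_VERSION)) {
    stop("unsupported native graph format version")
  }
  snapshot <- tryCatch(unserialize(con),
                       error = function(e) stop("truncated or corrupt native graph file"))
  g <- vg_new()
  for (k in names(snapshot$nodes)) assign(k, snapshot$nodes[[k]], envir = g$nodes)
  for (k in names(snapshot$paths)) assign(k, snapshot$paths[[k]], envir = g$paths)
  for (k in names(snapshot$path_names)) assign(k, snapshot$path_names[[k]], envir = g$path_names)
  for (k in names(snapshot$seg_names)) assign(k, snapshot$seg_names[[k]], envir = g$seg_names)
  g$path_order <- snapshot$path_order
  g$next_path_id <- snapshot$next_path_id
  g$max_id <- snapshot$max_id
  g$min_id <- snapshot$min_id
  g
}
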