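# Node strands ("handles"): one orientation of a node. A handle is a plain
# list(id, rev) so it can round-trip through user input as "12+", "12-",
# a bare id (forward), or vg_handle(id, rev).

#' Create a node-strand handle
#'
#' A handle designates one strand of a node: the stored (forward) sequence or
#' its implicit reverse complement.
#'
#' @param id Positive integer node identifier.
#' @param rev Logical; `TRUE` selects the reverse-complement strand.
#' @return An object of class `vg_handle`.
#' @examples
#' h <- vg_handle(3, TRUE)
#' handle_flip(h)
#' @export
vg_handle <- function(id, rev = FALSE) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stop("handle id must be a positive integer")
  structure(list(id = id, rev = isTRUE(rev)), class = "vg_handle")
}

#' @rdname vg_handle
#' @param h A handle.
#' @export
handle_id <- function(h) h$id

#' @rdname vg_handle
#' @export
handle_is_rev <- function(h) h$rev

#' Flip a handle to the opposite strand
#'
#' `handle_flip(handle_flip(h))` is `h`.
#'
#' @param h A handle (see [vg_handle()]).
#' @return The handle for the opposite strand of the same node.
#' @export
handle_flip <- function(h) {
  h <- as_handle(h)
  vg_handle(h$id, !h$rev)
}

#' Coerce to a handle
#'
#' Accepts a `vg_handle`, a bare positive integer (forward strand), or a
#' string such as `"12+"` / `"12-"`.
#'
#' @param x Object to coerce.
#' @return A `vg_handle`.
#' @export
as_handle <- function(x) {
  if (inherits(x, "vg_handle")) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^([0-9]+)([+-])$", x))[[1]]
    if (length(m) == 3L) return(vg_handle(as.integer(m[2]), m[3] == "-"))
    stop("cannot parse handle from string: ", x)
  }
  if (is.numeric(x) && length(x) == 1L) return(vg_handle(x, FALSE))
  if (is.numeric(x) && length(x) == 2L) return(vg_handle(x[1], as.logical(x[2])))
  stop("cannot coerce to handle")
}

#' @export
format.vg_handle <- function(x, ...) paste0(x$id, if (x$rev) "-" else "+")

#' @export
print.vg_handle <- function(x, ...) {
  cat("<handle ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Delta-encode the difference between two node ids
#'
#' Adjacency and path-step links are stored as relative id differences
#' rather than absolute identifiers: `delta = id_from - id_to`. The inverse
#' is [delta_decode()].
#'
#' @param id_from,id_to Positive integer node ids.
#' @return Signed integer difference.
#' @examples
#' delta_encode(5, 3)          # +2
#' delta_decode(5, delta_encode(5, 3))  # 3
#' @export
delta_encode <- function(id_from, id_to) {
  as.integer(id_from) - as.integer(id_to)
}

#' @rdname delta_encode
#' @param delta Signed integer produced by [delta_encode()].
#' @export
delta_decode <- function(id_from, delta) {
  as.integer(id_from) - as.integer(delta)
}

# reverse complement over {A,C,G,T,N}; lower case normalized on input paths
revcomp <- function(s) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
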