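#' Shift distance between two strings
#'
#' The asymmetric integer metric underlying the overlap graph: the minimal
#' number of positions string `b` must be shifted to the right so that its
#' prefix coincides with a suffix of string `a` *and* `b` reaches or passes
#' the end of `a` (it may overhang by zero characters, but may not stop
#' before `a` ends).  If no non-empty suffix of `a` matches a prefix of `b`,
#' the empty overlap applies and the distance is `nchar(a)`.
#'
#' Requiring the overhang makes the metric satisfy the triangle inequality
#' and lets a packing path resume from the last site placed.
#'
#' @param a,b Non-empty strings over a common alphabet.
#' @return A non-negative integer in `[0, nchar(a)]`.
#' @examples
#' shift_distance("AGC", "CAG")    # 2
#' shift_distance("CAG", "AGC")    # 1
#' shift_distance("CGT", "CAG")    # 3 (empty-overlap fallback)
#' shift_distance("AGCAG", "GC")   # 4, not 1: GC must cover the end
#' @export
shift_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b)) {
    stop("'a' and 'b' must be single strings", call. = FALSE)
  }
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0L || nb == 0L) {
    stop("shift_distance is undefined for empty strings", call. = FALSE)
  }
  # k + nb >= na guarantees b covers the end of a
  for (k in max(0L, na - nb):(na - 1L)) {
    if (substr(a, k + 1L, na) == substr(b, 1L, na - k)) {
      return(k)
    }
  }
  na
}

#' Build the overlap graph of a site collection
#'
#' Constructs the complete directed graph on which the packing problem is
#' solved as an Orienteering Problem.  Each binding site becomes a vertex
#' (two vertices in double-strand mode: the site and its reverse complement);
#' the edge weight from vertex `i` to vertex `j` is the shift distance
#' [shift_distance()] between their sequences.  Conceptually the graph also
#' holds a start vertex at distance 0 from every site and an end vertex at
#' distance `nchar(site)` from each site; these two are implicit here and
#' materialized by [build_model()] as index 0.
#'
#' Fixed promoter elements (sites flagged `fixed` in the collection) are kept
#' on the forward strand only, even in double-strand mode.
#'
#' @param collection A [site_collection()].
#' @param strands `"single"` or `"double"`.  Double-strand mode requires a
#'   complement map on the collection.
#' @return An object of class `overlap_graph` with a vertex table and the
#'   dense integer matrix `d` of shift distances between internal vertices.
#' @examples
#' g <- build_graph(site_collection(c("AGC", "CAG", "GCA")), "single")
#' g$d
#' @export
build_graph <- function(collection, strands = c("double", "single")) {
  strands <- match.arg(strands)
  stopifnot(inherits(collection, "site_collection"))
  st <- collection$sites
  if (strands == "double") {
    if (is.null(collection$complement)) {
      stop("double-strand mode requires a complement map on the collection",
           call. = FALSE)
    }
    fwd <- data.frame(site_id = st$id, orientation = "fwd", seq = st$seq,
                      fixed = st$fixed, stringsAsFactors = FALSE)
    dup <- st[!st$fixed, , drop = FALSE]
    rev <- if (nrow(dup)) {
      data.frame(site_id = dup$id, orientation = "rev",
                 seq = reverse_complement(dup$seq, collection$complement),
                 fixed = dup$fixed, stringsAsFactors = FALSE)
    } else {
      fwd[0, ]
    }
    vt <- rbind(fwd, rev)
  } else {
    vt <- data.frame(site_id = st$id, orientation = "fwd", seq = st$seq,
                     fixed = st$fixed, stringsAsFactors = FALSE)
  }
  vt$length <- nchar(vt$seq)
  vt <- vt[, c("site_id", "orientation", "seq", "length", "fixed")]
  n <- nrow(vt)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- shift_distance(vt$seq[i], vt$seq[j])
    }
  }
  dimnames(d) <- list(paste0(vt$site_id, ifelse(vt$orientation == "rev", "'", "")),
                      paste0(vt$site_id, ifelse(vt$orientation == "rev", "'", "")))
  structure(
    list(vertices = vt, d = d, strands = strands, collection = collection),
    class = "overlap_graph"
  )
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf(
    "Overlap graph: %d internal vertices (+start/end), %s-strand\n",
    nrow(x$vertices), x$strands))
  if (nrow(x$vertices) <= 12L) {
    print(x$d)
  }
  invisible(x)
}
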