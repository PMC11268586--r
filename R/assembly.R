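#' Reconstruct the nucleotide sequence from a solved path
#'
#' Overlays the oriented site strings at their cumulative shift offsets along
#' the path.  The shift metric guarantees that characters agree wherever two
#' placements overlap; the overlay is asserted anyway, so a disagreement
#' surfaces as an internal-consistency error rather than silent corruption.
#'
#' @param path Integer vector of internal vertex indices in path order
#'   (empty for the start->end path).
#' @param graph The [overlap_graph][build_graph] the path refers to.
#' @param L Length budget; the used length must not exceed it.
#' @return An object of class `packing`: placements (site id, orientation,
#'   0-based offset, length), the assembled sequence, `used_length`,
#'   `base_score` and the independent `occurrence_count` from
#'   [verify_occurrences()].
#' @examples
#' g <- build_graph(site_collection(c("AGC", "CAG")), "single")
#' reconstruct(c(1L, 2L), g, 5)$sequence  # "AGCAG"
#' @export
reconstruct <- function(path, graph, L) {
  stopifnot(inherits(graph, "overlap_graph"))
  vt <- graph$vertices
  path <- as.integer(path)
  if (length(path) == 0L) {
    pl <- data.frame(site_id = character(0), orientation = character(0),
                     offset = integer(0), length = integer(0),
                     stringsAsFactors = FALSE)
    occ <- verify_occurrences("", graph$collection, graph$strands)
    return(structure(list(placements = pl, sequence = "", used_length = 0L,
                          base_score = 0L, objective_value = NA_real_,
                          occurrence_count = sum(occ)),
                     class = "packing"))
  }
  offsets <- integer(length(path))
  for (t in seq_along(path)[-1]) {
    offsets[t] <- offsets[t - 1L] + graph$d[path[t - 1L], path[t]]
  }
  used <- offsets[length(path)] + vt$length[path[length(path)]]
  if (used > L) {
    stop("internal error: reconstructed length ", used, " exceeds L = ", L,
         call. = FALSE)
  }
  chars <- rep(NA_character_, used)
  for (t in seq_along(path)) {
    v <- path[t]
    s <- strsplit(vt$seq[v], "")[[1]]
    span <- offsets[t] + seq_along(s)
    placed <- chars[span]
    if (any(!is.na(placed) & placed != s)) {
      stop("internal error: overlay disagreement at path step ", t,
           " (metric or solver bug)", call. = FALSE)
    }
    chars[span] <- s
  }
  if (anyNA(chars)) {
    stop("internal error: gap inside the assembled sequence", call. = FALSE)
  }
  pl <- data.frame(site_id = vt$site_id[path],
                   orientation = vt$orientation[path],
                   offset = offsets, length = vt$length[path],
                   stringsAsFactors = FALSE)
  seqs <- paste(chars, collapse = "")
  occ <- verify_occurrences(seqs, graph$collection, graph$strands)
  structure(list(placements = pl, sequence = seqs,
                 used_length = used, base_score = length(path),
                 objective_value = NA_real_,
                 occurrence_count = sum(occ)),
            class = "packing")
}

#' @export
print.packing <- function(x, ...) {
  cat(sprintf("Packing: %d sites, used length %d\n  %s\n",
              x$base_score, x$used_length, x$sequence))
  for (i in seq_len(nrow(x$placements))) {
    p <- x$placements[i, ]
    site <- strrep(" ", p$offset)
    cat(sprintf("  %s%s  %s(%s)\n", site,
                substr(x$sequence, p$offset + 1, p$offset + p$length),
                p$site_id, ifelse(p$orientation == "rev", "-", "+")))
  }
  if (x$occurrence_count > x$base_score) {
    cat(sprintf("  (%d sites occur in the sequence, %d on the path)\n",
                x$occurrence_count, x$base_score))
  }
  invisible(x)
}

#' Scan a sequence for binding-site occurrences
#'
#' Independent validation of a packing claim: an exact substring scan of the
#' forward strand, plus (in double-strand mode) a scan for each site's
#' reverse complement.  A site is present if it occurs anywhere, whether or
#' not it was on the solver's path, so the count can exceed the ILP base
#' score when a site occurs incidentally.
#'
#' @param sequence A single string (possibly empty).
#' @param collection The [site_collection()] to scan for.
#' @param strands `"single"` or `"double"`.
#' @return Named logical vector over the collection's site ids.
#' @examples
#' verify_occurrences("AGCAG", site_collection(c("AGC", "GC")), "single")
#' @export
verify_occurrences <- function(sequence, collection,
                               strands = c("double", "single")) {
  strands <- match.arg(strands)
  stopifnot(inherits(collection, "site_collection"))
  st <- collection$sites
  found <- vapply(seq_len(nrow(st)), function(i) {
    if (nchar(sequence) == 0L) return(FALSE)
    hit <- grepl(st$seq[i], sequence, fixed = TRUE)
    if (!hit && strands == "double" && !st$fixed[i]) {
      hit <- grepl(reverse_complement(st$seq[i], collection$complement),
                   sequence, fixed = TRUE)
    }
    hit
  }, logical(1))
  stats::setNames(found, st$id)
}

#' Pad an assembled sequence to the full target length
#'
#' The solver reports the core sequence, whose used length may fall short of
#' `L`.  Padding appends `N`s or seeded random bases on the right; random
#' padding re-scans the result and warns when the filler created new site
#' occurrences.
#'
#' @param packing A [packing][reconstruct] (or any list with `sequence` and
#'   `used_length`).
#' @param L Target length.
#' @param mode `"none"` (return the core), `"N"`, or `"random"`.
#' @param seed Integer seed for random padding.
#' @param collection Collection used for the post-padding occurrence scan
#'   (and for the padding alphabet); optional for modes `"none"` and `"N"`.
#' @param strands Strand mode for the re-scan.
#' @return A single string: the core (mode `"none"`) or a length-`L` string.
#' @export
pad_sequence <- function(packing, L, mode = c("none", "N", "random"),
                         seed = NULL, collection = NULL,
                         strands = c("double", "single")) {
  mode <- match.arg(mode)
  strands <- match.arg(strands)
  core <- packing$sequence
  deficit <- L - nchar(core)
  if (deficit < 0L) stop("sequence longer than L", call. = FALSE)
  if (mode == "none" || deficit == 0L) return(core)
  if (mode == "N") return(paste0(core, strrep("N", deficit)))
  alphabet <- if (!is.null(collection)) collection$alphabet else c("A", "C", "G", "T")
  filler <- with_rng_seed(seed, paste(sample(alphabet, deficit, replace = TRUE),
                                      collapse = ""))
  padded <- paste0(core, filler)
  if (!is.null(collection)) {
    before <- verify_occurrences(core, collection, strands)
    after <- verify_occurrences(padded, collection, strands)
    gained <- names(after)[after & !before]
    if (length(gained)) {
      warning("random padding created new occurrence(s) of: ",
              paste(gained, collapse = ", "), call. = FALSE)
    }
  }
  padded
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; a NULL seed leaves the RNG untouched.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}
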