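#' DNA complement map
#'
#' The standard Watson-Crick pairing used as the default complement map for
#' double-strand optimization: A<->T, C<->G.
#'
#' @return A named character vector mapping each base to its complement.
#' @export
dna_complement <- function() {
  c(A = "T", C = "G", G = "C", T = "A")
}

#' Create a collection of binding sites
#'
#' A site collection bundles the alphabet, the binding-site strings with
#' stable identifiers, and (optionally) a complement map that enables
#' double-strand optimization.  Sequences are upper-cased; characters outside
#' the alphabet are an error, never dropped.
#'
#' @param sites Character vector of binding-site strings (non-empty).
#' @param ids Optional character vector of unique identifiers; defaults to
#'   `site1`, `site2`, ...
#' @param alphabet Character vector of allowed single characters.  Defaults to
#'   the DNA alphabet A, C, G, T.
#' @param complement Named character vector giving the complement of each
#'   alphabet character (an involution), or `NULL` for alphabets without a
#'   complement.  Defaults to [dna_complement()] when the alphabet is DNA.
#' @return An object of class `site_collection`.
#' @examples
#' site_collection(c("AGC", "CAG", "GCA"))
#' @export
site_collection <- function(sites, ids = NULL,
                            alphabet = c("A", "C", "G", "T"),
                            complement = NULL) {
  if (length(sites) < 1L) {
    stop("a site collection needs at least one site", call. = FALSE)
  }
  if (!is.character(sites) || anyNA(sites)) {
    stop("'sites' must be a character vector without NA", call. = FALSE)
  }
  sites <- toupper(sites)
  if (any(nchar(sites) == 0L)) {
    stop("binding sites must be non-empty strings", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- paste0("site", seq_along(sites))
  }
  ids <- as.character(ids)
  if (length(ids) != length(sites)) {
    stop("'ids' must match 'sites' in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("site ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  alphabet <- toupper(as.character(alphabet))
  if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
    stop("'alphabet' must be distinct single characters", call. = FALSE)
  }
  bad <- !vapply(strsplit(sites, ""), function(ch) all(ch %in% alphabet),
                 logical(1))
  if (any(bad)) {
    stop("site(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside the alphabet {",
         paste(alphabet, collapse = ","), "}", call. = FALSE)
  }
  if (is.null(complement) && setequal(alphabet, c("A", "C", "G", "T"))) {
    complement <- dna_complement()
  }
  if (!is.null(complement)) {
    complement <- toupper(complement)
    names(complement) <- toupper(names(complement))
    if (!setequal(names(complement), alphabet)) {
      stop("'complement' must be defined on exactly the alphabet", call. = FALSE)
    }
    # involution: complement of complement is the identity
    if (!identical(unname(complement[complement[alphabet]]), alphabet)) {
      stop("'complement' must be an involution on the alphabet", call. = FALSE)
    }
  }
  structure(
    list(
      sites = data.frame(id = ids, seq = sites, length = nchar(sites),
                         fixed = FALSE, stringsAsFactors = FALSE),
      alphabet = alphabet,
      complement = complement
    ),
    class = "site_collection"
  )
}

#' @export
print.site_collection <- function(x, ...) {
  cat(sprintf("Site collection: %d sites over {%s}%s\n",
              nrow(x$sites), paste(x$alphabet, collapse = ","),
              if (is.null(x$complement)) " (no complement map)" else ""))
  n <- nrow(x$sites)
  show <- utils::head(x$sites, 10L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-12s %s%s\n", show$id[i], show$seq[i],
                if (show$fixed[i]) "  [fixed element]" else ""))
  }
  if (n > 10L) cat(sprintf("  ... and %d more\n", n - 10L))
  invisible(x)
}

#' @export
length.site_collection <- function(x) nrow(x$sites)

#' Reverse complement of a string
#'
#' Reverses the string and substitutes each character by its complement.
#' Applying the operation twice returns the input.
#'
#' @param s Character vector of strings to reverse-complement.
#' @param complement Named character vector (an involution); defaults to the
#'   DNA map from [dna_complement()].
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("AGC")  # "GCT"
#' @export
reverse_complement <- function(s, complement = dna_complement()) {
  if (is.null(complement)) {
    stop("no complement map available (alphabet without complements)",
         call. = FALSE)
  }
  vapply(as.character(s), function(x) {
    ch <- strsplit(x, "")[[1]]
    if (!all(ch %in% names(complement))) {
      stop("character(s) without a complement in '", x, "'", call. = FALSE)
    }
    paste(rev(unname(complement[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Append fixed promoter elements to a collection as forward-only sites.
# Returns the enlarged collection; element ids must not collide.
collection_add_fixed <- function(collection, seqs, ids) {
  seqs <- toupper(seqs)
  for (s in seqs) {
    if (!all(strsplit(s, "")[[1]] %in% collection$alphabet)) {
      stop("fixed element '", s, "' contains characters outside the alphabet",
           call. = FALSE)
    }
  }
  if (any(ids %in% collection$sites$id)) {
    stop("fixed element id collides with a site id", call. = FALSE)
  }
  add <- data.frame(id = ids, seq = seqs, length = nchar(seqs), fixed = TRUE,
                    stringsAsFactors = FALSE)
  collection$sites <- rbind(collection$sites, add)
  collection
}
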