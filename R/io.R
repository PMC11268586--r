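#' Read binding sites from a file
#'
#' FASTA input (record id becomes the site id) or plain text with one site
#' per line (blank lines skipped, sites auto-numbered `site1`, `site2`, ...).
#' Sequences are upper-cased; characters outside the alphabet raise a parse
#' error naming the offending record, never a silent drop.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"lines"`; default guesses from the extension
#'   (`.fa`, `.fasta`, `.fna` are FASTA).
#' @param alphabet Allowed characters; default DNA.
#' @return A [site_collection()].
#' @export
read_sites <- function(path, format = c("auto", "fasta", "lines"),
                       alphabet = c("A", "C", "G", "T")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta" else "lines"
  }
  if (format == "fasta") {
    recs <- tryCatch(
      seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                         seqtype = "AA"),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
    seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
    ids <- names(recs)
  } else {
    lines <- toupper(trimws(readLines(path, warn = FALSE)))
    keep <- nzchar(lines)
    if (!any(keep)) stop("no sites in ", path, call. = FALSE)
    bad <- which(keep & grepl("[^A-Z]", lines))
    seqs <- lines[keep]
    ids <- paste0("site", seq_along(seqs))
  }
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    if (!all(ch %in% toupper(alphabet))) {
      stop("record '", ids[i], "' in ", path,
           " contains characters outside the alphabet {",
           paste(alphabet, collapse = ","), "}", call. = FALSE)
    }
  }
  site_collection(seqs, ids = ids, alphabet = alphabet)
}

#' Write packed arrays to FASTA
#'
#' One record per solution with header `arrayK score=S used=U L=L`.
#'
#' @param fit A [dense_packing][pack_sites] object.
#' @param path Output path.
#' @param pad Padding mode for sequences shorter than `L` (see
#'   [pad_sequence()]).
#' @param seed Seed for random padding.
#' @return The path, invisibly.
#' @export
write_packings_fasta <- function(fit, path, pad = "none", seed = NULL) {
  stopifnot(inherits(fit, "dense_packing"))
  seqs <- lapply(seq_along(fit$packings), function(i) {
    pad_sequence(fit$packings[[i]], fit$L, mode = pad, seed = seed,
                 collection = fit$collection, strands = fit$strands)
  })
  names(seqs) <- vapply(seq_along(fit$packings), function(i) {
    p <- fit$packings[[i]]
    sprintf("array%d score=%d used=%d L=%d", i, p$base_score, p$used_length,
            fit$L)
  }, character(1))
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path,
                      as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' JSON report of a packing run
#'
#' Machine-readable companion to the FASTA output: backend, seed, optimal
#' score, solutions with 0-based placements (half-open intervals), usage
#' counts and the entropy trace.
#'
#' @param fit A [dense_packing][pack_sites] object.
#' @param path Output path (`NULL` returns the report list).
#' @return The report list, invisibly when written.
#' @export
packing_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dense_packing"))
  report <- list(
    backend = fit$backend,
    seed = fit$seed,
    L = fit$L,
    strands = fit$strands,
    order = fit$order,
    S_star = fit$S_star,
    termination = fit$termination,
    solutions = lapply(fit$packings, function(p) {
      list(sequence = p$sequence, used_length = p$used_length,
           base_score = p$base_score, objective = p$objective_value,
           occurrence_count = p$occurrence_count,
           placements = p$placements)
    }),
    usage_counts = as.list(fit$counts),
    entropy_trace = fit$entropy_trace
  )
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Read a constraint configuration file
#'
#' YAML or JSON with the schema
#' \preformatted{
#' elements:
#'   - seq: TTGACA
#'     start: [40, 60]
#'     pair: {seq: TATAAT, spacer: [16, 18]}
#' biases: {site3: upstream, site7: downstream}
#' epsilon: 0.05
#' spacer_convention: gap
#' }
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with `elements` (list of [fixed_element()]), `biases`,
#'   `epsilon`, `spacer_convention` (absent entries are `NULL`).
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  elements <- lapply(cfg$elements, function(e) {
    fixed_element(e$seq, unlist(e$start),
                  pair = if (!is.null(e$pair)) {
                    list(seq = e$pair$seq, spacer = unlist(e$pair$spacer))
                  })
  })
  biases <- if (!is.null(cfg$biases)) unlist(cfg$biases)
  list(elements = elements, biases = biases, epsilon = cfg$epsilon,
       spacer_convention = cfg$spacer_convention)
}
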