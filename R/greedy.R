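#' Greedy superstring by repeated best-overlap merging
#'
#' The classical greedy shortest-common-superstring heuristic: repeatedly
#' merge the ordered pair of strings with the largest overlap
#' (`nchar(a) - shift_distance(a, b)`) until a single string containing
#' every input site remains.  A string fully contained in another counts as
#' overlapping by its whole length and is absorbed.  Ties are broken towards
#' the smallest (first index, second index) pair, making the result
#' deterministic.
#'
#' @param collection A [site_collection()].
#' @return A single superstring containing every site of the collection.
#' @examples
#' greedy_superstring(site_collection(c("AGC", "GCA")))  # "AGCA"
#' @export
greedy_superstring <- function(collection) {
  stopifnot(inherits(collection, "site_collection"))
  pool <- collection$sites$seq
  while (length(pool) > 1L) {
    best <- c(-1L, 0L, 0L)  # overlap, i, j
    merged_best <- NULL
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i == j) next
        a <- pool[i]; b <- pool[j]
        if (grepl(b, a, fixed = TRUE)) {
          ov <- nchar(b)
          merged <- a
        } else {
          dd <- shift_distance(a, b)
          ov <- nchar(a) - dd
          merged <- paste0(substr(a, 1L, dd), b)
        }
        if (ov > best[1]) {
          best <- c(ov, i, j)
          merged_best <- merged
        }
      }
    }
    i <- best[2]; j <- best[3]
    pool[i] <- merged_best
    pool <- pool[-j]
  }
  pool
}

#' Densest length-L window of a superstring
#'
#' If the superstring already fits the budget it is returned whole (it then
#' contains every site and is an optimal packing).  Otherwise every length-`L`
#' window is scanned and the one fully containing the most sites (counting
#' reverse-complement occurrences in double mode) is returned; ties go to the
#' leftmost window.
#'
#' @param superstring A single string, typically from [greedy_superstring()].
#' @param collection The originating [site_collection()].
#' @param L Window length (`L >= 1`).
#' @param strands `"single"` or `"double"`.
#' @return A list: `sequence`, `offset` (0-based window start in the
#'   superstring), `count`, and `present` (named logical per site).
#' @export
densest_window <- function(superstring, collection, L,
                           strands = c("double", "single")) {
  strands <- match.arg(strands)
  stopifnot(inherits(collection, "site_collection"), L >= 1)
  ns <- nchar(superstring)
  if (ns <= L) {
    present <- verify_occurrences(superstring, collection, strands)
    return(list(sequence = superstring, offset = 0L,
                count = sum(present), present = present))
  }
  starts <- 0:(ns - L)
  counts <- vapply(starts, function(s) {
    sum(verify_occurrences(substr(superstring, s + 1L, s + L),
                           collection, strands))
  }, numeric(1))
  s <- starts[which.max(counts)]  # which.max takes the leftmost tie
  win <- substr(superstring, s + 1L, s + L)
  present <- verify_occurrences(win, collection, strands)
  list(sequence = win, offset = s, count = sum(present), present = present)
}

#' Greedy approximation of the packing problem
#'
#' The polynomial-time baseline: build the greedy superstring, then extract
#' its densest length-`L` window.  Its count never exceeds the ILP optimum
#' and reaches it whenever the whole superstring fits the budget.
#'
#' @param collection A [site_collection()].
#' @param L Length budget.
#' @param strands `"single"` or `"double"`.
#' @return As [densest_window()], plus `method = "greedy"` and the
#'   intermediate `superstring`.
#' @export
greedy_pack <- function(collection, L, strands = c("double", "single")) {
  strands <- match.arg(strands)
  ss <- greedy_superstring(collection)
  out <- densest_window(ss, collection, L, strands)
  out$superstring <- ss
  out$method <- "greedy"
  out
}
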