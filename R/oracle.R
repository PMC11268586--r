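# Brute-force references.  These deliberately share nothing with the ILP
# machinery beyond the overlap graph itself: the path search is a plain
# depth-first enumeration (no MTZ, no solver), and the sequence search
# enumerates raw strings, so either can serve as an independent check.

#' Exhaustive path search for the optimal packing
#'
#' Depth-first enumeration of all simple start->...->end paths within the
#' length budget, honoring the strand-exclusion rule in double mode.
#' Returns the maximum number of sites on any such path together with every
#' distinct assembled sequence achieving it.  Factorial search: refuses
#' instances with more than `max_vertices` internal vertices.
#'
#' @param collection A [site_collection()].
#' @param L Length budget.
#' @param strands `"single"` or `"double"`.
#' @param max_vertices Size guard on the internal vertex count (default 9).
#' @return A list: `score`, `sequences` (sorted unique optimal sequences),
#'   `n_optimal_paths`.
#' @examples
#' brute_force_pack(site_collection(c("AGC", "CAG", "GCA")), 5, "single")$score
#' @export
brute_force_pack <- function(collection, L, strands = c("double", "single"),
                             max_vertices = 9L) {
  strands <- match.arg(strands)
  graph <- build_graph(collection, strands)
  vt <- graph$vertices
  n <- nrow(vt)
  if (n > max_vertices) {
    stop("instance too large for the brute-force oracle (", n, " > ",
         max_vertices, " internal vertices)", call. = FALSE)
  }
  d <- graph$d
  len <- vt$length
  # vertices sharing a site id block each other (strand exclusion)
  mates <- lapply(seq_len(n), function(v) which(vt$site_id == vt$site_id[v]))
  env <- new.env(parent = emptyenv())
  env$best <- 0L
  env$paths <- list(integer(0))
  blocked <- rep(FALSE, n)
  recurse <- function(last, cost, count, path) {
    if (count > env$best) {
      env$best <- count
      env$paths <- list(path)
    } else if (count == env$best) {
      env$paths[[length(env$paths) + 1L]] <- path
    }
    for (v in seq_len(n)) {
      if (blocked[v]) next
      step <- if (last == 0L) 0L else d[last, v]
      if (cost + step + len[v] > L) next
      blocked[mates[[v]]] <<- TRUE
      recurse(v, cost + step, count + 1L, c(path, v))
      blocked[mates[[v]]] <<- FALSE
    }
  }
  recurse(0L, 0L, 0L, integer(0))
  seqs <- vapply(env$paths, function(p) reconstruct(p, graph, L)$sequence,
                 character(1))
  list(score = env$best, sequences = sort(unique(seqs)),
       n_optimal_paths = length(env$paths))
}

#' Exhaustive search over all length-L strings
#'
#' The raw brute force the graph reduction avoids: enumerate every string of
#' length `L` over the alphabet and count contained sites (both strands in
#' double mode).  Unlike the path search this also credits sites that occur
#' incidentally inside other sites, so its optimum can exceed the path
#' oracle's.  Refuses search spaces larger than `max_space` strings.
#'
#' @param collection A [site_collection()].
#' @param L String length (`L = 0` returns 0).
#' @param strands `"single"` or `"double"`.
#' @param max_space Guard on `|alphabet|^L` (default `1e7`).
#' @return The maximum number of collection sites contained in any
#'   length-`L` string.
#' @export
exhaustive_sequence_search <- function(collection, L,
                                       strands = c("double", "single"),
                                       max_space = 1e7) {
  strands <- match.arg(strands)
  stopifnot(inherits(collection, "site_collection"))
  L <- as.integer(L)
  if (L <= 0L) return(0L)
  k <- length(collection$alphabet)
  if (k^L > max_space) {
    stop("search space ", k, "^", L, " exceeds the size limit", call. = FALSE)
  }
  pool <- ""
  for (i in seq_len(L)) {
    pool <- as.vector(outer(pool, collection$alphabet, paste0))
  }
  hits <- integer(length(pool))
  st <- collection$sites
  for (i in seq_len(nrow(st))) {
    pats <- st$seq[i]
    if (strands == "double" && !st$fixed[i]) {
      pats <- unique(c(pats, reverse_complement(st$seq[i], collection$complement)))
    }
    found <- rep(FALSE, length(pool))
    for (p in pats) found <- found | grepl(p, pool, fixed = TRUE)
    hits <- hits + found
  }
  max(hits)
}

# ---- exact big-integer arithmetic (base 1e4, little-endian) -------------
# Only what the path-count formula needs: multiply by a machine integer,
# add a machine integer, and read off decimal digits.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  v <- integer(0)
  while (x > 0) {
    v <- c(v, x %% 10000L)
    x <- x %/% 10000L
  }
  v
}

big_mul_small <- function(v, m) {
  prod <- as.numeric(v) * m
  carry <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(prod) || carry > 0) {
    t <- carry + if (i <= length(prod)) prod[i] else 0
    out[i] <- t %% 10000
    carry <- floor(t / 10000)
    i <- i + 1L
  }
  out
}

big_add_small <- function(v, a) {
  v[1] <- v[1] + a
  i <- 1L
  while (v[i] >= 10000) {
    carry <- floor(v[i] / 10000)
    v[i] <- v[i] %% 10000
    if (i == length(v)) v <- c(v, 0)
    v[i + 1L] <- v[i + 1L] + carry
    i <- i + 1L
  }
  v
}

big_to_string <- function(v) {
  v <- rev(v)
  paste0(v[1], paste(sprintf("%04d", v[-1]), collapse = ""))
}

#' Count the simple paths of the packing graph
#'
#' The number of ordered selections of internal vertices, i.e. of simple
#' start->...->end paths available to the Orienteering Problem on `n` sites:
#' `sum_{k=0}^{n} n!/(n-k)!`, computed in exact integer arithmetic via the
#' recurrence `a(n) = n a(n-1) + 1`.  For `|R| = 50` sites this is about
#' `1e65` paths -- astronomically many, yet far fewer than the `4^200`
#' strings a raw sequence enumeration would face at `L = 200`.
#'
#' @param n Number of internal vertices (`n >= 0`).
#' @return The exact count as a decimal string.
#' @examples
#' count_simple_paths(2)  # "5": {}, (1), (2), (1,2), (2,1)
#' round(decimal_log10(count_simple_paths(50)))  # 65
#' @export
count_simple_paths <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  a <- big_from_int(1)
  for (m in seq_len(n)) {
    a <- big_add_small(big_mul_small(a, m), 1)
  }
  big_to_string(a)
}

#' Exact integer power as a decimal string
#'
#' @param base,exponent Non-negative machine integers.
#' @return `base^exponent` as a decimal string (exact arithmetic).
#' @examples
#' exact_power(4, 200)
#' @export
exact_power <- function(base, exponent) {
  stopifnot(base >= 0, exponent >= 0)
  v <- big_from_int(1)
  for (i in seq_len(exponent)) v <- big_mul_small(v, base)
  big_to_string(v)
}

#' Base-10 logarithm of a decimal integer string
#'
#' @param x Non-negative integer given as a decimal string (as returned by
#'   [count_simple_paths()] or [exact_power()]).
#' @return `log10(x)` as a double.
#' @export
decimal_log10 <- function(x) {
  x <- as.character(x)
  stopifnot(grepl("^[0-9]+$", x))
  x <- sub("^0+(?=.)", "", x, perl = TRUE)
  if (x == "0") return(-Inf)
  nd <- nchar(x)
  lead <- as.numeric(substr(x, 1, min(nd, 15L)))
  log10(lead) + (nd - min(nd, 15L))
}
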