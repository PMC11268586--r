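# Shared model assembly used by pack_sites() and the simulation harnesses.
# Appends fixed elements to the collection as forward-only sites, builds the
# graph and the ILP, attaches positions when any extension needs them, and
# applies the halved perturbation budgets when diversity and side bias are
# both active (so their summed objective perturbation stays below 0.5).
build_packing_model <- function(collection, L, strands = "double",
                                elements = NULL, bias = NULL,
                                spacer_convention = "gap",
                                epsilon = NULL, K = NULL,
                                diversity = FALSE) {
  if (!inherits(collection, "site_collection")) {
    collection <- site_collection(collection)
  }
  elements <- lapply(elements, function(e) {
    if (!inherits(e, "fixed_element")) {
      e <- fixed_element(e$seq, e$start, e$pair)
    }
    e
  })
  if (length(elements)) {
    for (i in seq_along(elements)) {
      elements[[i]]$id <- sprintf("element%d", i)
      if (!is.null(elements[[i]]$pair)) {
        elements[[i]]$pair_id <- sprintf("element%d_pair", i)
      }
    }
    seqs <- unlist(lapply(elements, function(e) c(e$seq, e$pair$seq)))
    ids <- unlist(lapply(elements, function(e) c(e$id, e$pair_id)))
    collection <- collection_add_fixed(collection, seqs, ids)
  }
  graph <- build_graph(collection, strands)
  n <- nrow(graph$vertices)
  both <- diversity && length(bias) > 0L
  if (is.null(epsilon)) epsilon <- if (both) 0.25 / n else 0.5 / n
  model <- build_model(graph, L, epsilon = epsilon)
  if (length(elements) || length(bias)) {
    model <- attach_positions(model)
  }
  for (e in elements) {
    model <- add_fixed_element(model, e, spacer_convention = spacer_convention)
  }
  if (length(bias)) {
    if (is.null(K)) K <- (if (both) 4 else 2) * n * max(L - 1, 1)
    model <- add_side_bias(model, bias, K = K)
  }
  list(model = model, graph = graph, collection = collection,
       elements = elements)
}

#' Pack binding sites into a dense array
#'
#' The front door of the package: finds nucleotide sequences of length at
#' most `L` containing as many of the collection's binding sites as possible
#' (allowing overlaps and, in double-strand mode, reverse-complement
#' placements), by solving the Orienteering-Problem ILP over the overlap
#' graph.  Optionally enumerates several distinct optimal sequences, in
#' solver order or diversity-driven order, honors fixed promoter elements
#' with start/spacer windows, and biases chosen sites towards the upstream
#' or downstream end of the array.
#'
#' @param x A [site_collection()], or a character vector of DNA site strings.
#' @param L Target sequence length in base pairs.
#' @param strands `"double"` (default; sites may appear as reverse
#'   complements, but never together with their own reverse complement) or
#'   `"single"`.
#' @param solutions Number of distinct optimal sequences to return.
#' @param order `"solver"` or `"diversity"` enumeration order.
#' @param elements Optional list of [fixed_element()]s (or bare lists with
#'   `seq`, `start`, `pair`).
#' @param bias Optional named character vector mapping site ids to
#'   `"upstream"`/`"downstream"`.
#' @param spacer_convention `"gap"` (spacer measured from the end of the
#'   upstream element) or `"printed"` (see [add_fixed_element()]).
#' @param epsilon,K Optional overrides of the diversity weight increment and
#'   the side-bias scale.
#' @param backend MILP backend (see [available_backends()]).
#' @param time_limit Per-solve limit in seconds.
#' @param seed Integer seed recorded in the run and used for any padding
#'   randomness.
#' @return An object of class `dense_packing`.
#' @examples
#' \donttest{
#' if (length(available_backends())) {
#'   fit <- pack_sites(c("AGC", "CAG", "GCA"), L = 5, strands = "single")
#'   fit$S_star           # 3 sites fit in 5 bp
#'   fit$packings[[1]]
#' }
#' }
#' @export
pack_sites <- function(x, L, strands = c("double", "single"),
                       solutions = 1L, order = c("solver", "diversity"),
                       elements = NULL, bias = NULL,
                       spacer_convention = c("gap", "printed"),
                       epsilon = NULL, K = NULL,
                       backend = "glpk", time_limit = 60, seed = 1L) {
  strands <- match.arg(strands)
  order <- match.arg(order)
  spacer_convention <- match.arg(spacer_convention)
  built <- build_packing_model(x, L, strands = strands, elements = elements,
                               bias = bias,
                               spacer_convention = spacer_convention,
                               epsilon = epsilon, K = K,
                               diversity = order == "diversity")
  enum <- enumerate_optimal(built$model, order = order, limit = solutions,
                            backend = backend, time_limit = time_limit,
                            seed = seed)
  structure(
    list(packings = enum$packings, S_star = enum$S_star,
         counts = enum$counts, entropy_trace = enum$entropy_trace,
         termination = enum$termination, reports = enum$reports,
         collection = built$collection, graph = built$graph,
         L = as.integer(L), strands = strands, order = order,
         elements = built$elements, bias = bias,
         backend = backend, seed = seed, call = match.call()),
    class = "dense_packing"
  )
}

#' @export
print.dense_packing <- function(x, ...) {
  cat(sprintf("Dense packing of %d sites into L = %d bp (%s strand, %s order)\n",
              sum(!x$collection$sites$fixed), x$L, x$strands, x$order))
  if (x$termination == "infeasible") {
    cat("  no feasible solution under the given constraints\n")
    return(invisible(x))
  }
  cat(sprintf("  optimal score S* = %d; %d distinct optimal sequence(s) returned (%s)\n",
              x$S_star, length(x$packings), x$termination))
  if (length(x$packings)) {
    cat("\nFirst solution:\n")
    print(x$packings[[1]])
  }
  invisible(x)
}

#' @export
summary.dense_packing <- function(object, ...) {
  freq <- if (length(object$packings)) {
    object$counts / length(object$packings)
  } else {
    object$counts
  }
  out <- list(
    S_star = object$S_star,
    n_solutions = length(object$packings),
    termination = object$termination,
    frequencies = sort(freq, decreasing = TRUE),
    entropy = if (length(object$entropy_trace)) {
      object$entropy_trace[length(object$entropy_trace)]
    } else {
      NA_real_
    },
    max_entropy = log(length(object$counts))
  )
  class(out) <- "summary.dense_packing"
  out
}

#' @export
print.summary.dense_packing <- function(x, ...) {
  cat(sprintf("S* = %s with %d distinct optimal sequence(s) [%s]\n",
              x$S_star, x$n_solutions, x$termination))
  cat("Site usage frequencies (sorted):\n")
  print(round(x$frequencies, 3))
  cat(sprintf("Usage entropy: %.4f nats (max %.4f)\n", x$entropy, x$max_entropy))
  invisible(x)
}

#' @export
as.data.frame.dense_packing <- function(x, ...) {
  if (!length(x$packings)) {
    return(data.frame(solution = integer(0), site_id = character(0),
                      orientation = character(0), offset = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(x$packings), function(i) {
    pl <- x$packings[[i]]$placements
    if (!nrow(pl)) return(NULL)
    cbind(data.frame(solution = i), pl)
  }))
}

#' Plot a dense packing run
#'
#' Two panels: the per-solution entropy trace of site usage (with the
#' `log(|R|)` uniform ceiling) and the sorted site-usage frequency curve,
#' the flatter the more uniformly sites were represented.
#'
#' @param x A `dense_packing` object.
#' @param ... Unused.
#' @export
plot.dense_packing <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (length(x$entropy_trace)) {
    plot(seq_along(x$entropy_trace), x$entropy_trace, type = "b", pch = 16,
         xlab = "solutions returned", ylab = "usage entropy (nats)",
         ylim = c(0, log(length(x$counts))),
         main = sprintf("entropy trace (%s order)", x$order))
    graphics::abline(h = log(length(x$counts)), lty = 2)
  }
  freq <- sort(x$counts / max(1, length(x$packings)), decreasing = TRUE)
  plot(seq_along(freq), freq, type = "h", lwd = 3,
       xlab = "site rank", ylab = "inclusion frequency",
       main = "sorted usage frequencies")
  invisible(x)
}
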