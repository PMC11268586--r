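#' Shannon entropy of site-usage counts
#'
#' Entropy (natural log) of the count-normalized frequency distribution of
#' binding-site usage across returned solutions.  The theoretical maximum is
#' `log(|R|)`, reached only when all sites have been involved uniformly.
#'
#' @param counts Non-negative numeric vector (named by site id) with at
#'   least one positive entry.
#' @return Entropy in nats, within `[0, log(length(counts))]`.
#' @examples
#' usage_entropy(rep(1, 10))  # log(10)
#' @export
usage_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("'counts' must be non-negative", call. = FALSE)
  }
  tot <- sum(counts)
  if (tot == 0) {
    stop("entropy undefined for all-zero counts", call. = FALSE)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Enumerate distinct top-scoring packings
#'
#' Streams solutions of equal optimal base score.  The first solve
#' establishes the optimum `S*`; a constraint then pins the base score to
#' `S*` and, after each returned solution, a no-good cut excludes its exact
#' active-edge set so the next solve must find a different path.  Distinct
#' edge sets that assemble the same nucleotide string are de-duplicated, so
#' the stream contains distinct sequences.
#'
#' With `order = "diversity"` the objective is reweighted from the running
#' usage counts through [set_diversity_weights()] before every re-solve,
#' steering ties towards under-represented sites; with `order = "solver"`
#' ties fall wherever the backend happens to break them.
#'
#' @param model A [packing_model][build_model].
#' @param order `"solver"` or `"diversity"`.
#' @param limit Maximum number of solutions to return (may be `Inf`:
#'   enumeration then ends at exhaustion).
#' @param backend,time_limit Passed to [solve_once()].
#' @param seed Recorded in the reports for provenance (GLPK itself is
#'   deterministic).
#' @return A list: `packings` (list of [packing][reconstruct] objects),
#'   `S_star`, `counts` (site-usage counts), `entropy_trace` (nats, one
#'   entry per returned solution), `termination`
#'   (`"limit"`/`"exhausted"`/`"timeout"`), and `reports`.
#' @export
enumerate_optimal <- function(model, order = c("solver", "diversity"),
                              limit = Inf, backend = "glpk",
                              time_limit = 60, seed = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(model, "packing_model"))
  if (limit < 1) stop("'limit' must be at least 1", call. = FALSE)
  graph <- model$graph
  ids <- unique(graph$vertices$site_id[!graph$vertices$fixed])
  counts <- stats::setNames(numeric(length(ids)), ids)
  packings <- list()
  entropy_trace <- numeric(0)
  reports <- list()
  seen <- character(0)
  termination <- "exhausted"
  S_star <- NA_integer_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    res <- solve_once(model, backend = backend, time_limit = time_limit)
    res$report$seed <- if (is.null(seed)) NA_integer_ else seed
    reports[[iter]] <- res$report
    if (res$report$status == "timeout") {
      termination <- "timeout"
      break
    }
    if (res$report$status == "infeasible") {
      termination <- if (length(packings)) "exhausted" else "infeasible"
      break
    }
    if (res$report$status != "optimal") {
      termination <- res$report$status
      break
    }
    path <- extract_path(model, res$assignment)
    if (is.na(S_star)) {
      S_star <- length(path)
      model <- add_score_pin(model, S_star)
      if (S_star == 0L) {
        # only the empty packing exists at this budget
        pk <- reconstruct(integer(0), graph, model$L)
        pk$objective_value <- res$report$objective
        packings <- list(pk)
        break
      }
    }
    pk <- reconstruct(path, graph, model$L)
    pk$objective_value <- res$report$objective
    xact <- stats::na.omit(as.vector(model$xidx))
    active <- xact[res$assignment[xact] > 0.5]
    model <- add_no_good_cut(model, active, tag = sprintf("_%d", iter))
    if (!(pk$sequence %in% seen)) {
      seen <- c(seen, pk$sequence)
      packings[[length(packings) + 1L]] <- pk
      used <- unique(pk$placements$site_id)
      used <- used[used %in% names(counts)]
      counts[used] <- counts[used] + 1
      entropy_trace <- c(entropy_trace,
                         if (sum(counts) > 0) usage_entropy(counts) else NA_real_)
      if (length(packings) >= limit) {
        termination <- "limit"
        break
      }
    }
    if (order == "diversity") {
      model <- set_diversity_weights(model, counts)
    }
  }
  list(packings = packings, S_star = S_star, counts = counts,
       entropy_trace = entropy_trace, termination = termination,
       reports = reports, order = order)
}
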