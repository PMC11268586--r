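# Exact feasibility decision for element-constrained packings.
#
# Whether any packing satisfies a set of fixed-element constraints is a
# yes/no question that general MILP branch-and-bound answers very slowly on
# this model (the position-linking rows are weak big-M constraints).  The
# decider below exploits the problem's structure instead: every feasible
# packing is a chain of placements starting at position 0 whose consecutive
# position differences are exact shift distances, visiting each element
# vertex once inside its window.  A depth-first search over such chains --
# with exact once-only and strand-exclusion bookkeeping -- is made practical
# by a sound relaxation bound: arrival-offset sets computed by dynamic
# programming on the overlap graph with site reuse allowed.  If the
# relaxation says some pending element can no longer be reached, the branch
# is dead; if the search exhausts, the model is infeasible; any completed
# chain is a feasibility certificate (verified against the constraints).

# Reachable arrival offsets between all vertex pairs, allowing any vertex to
# be reused (a relaxation): A[[v]][w, delta + 1] is TRUE when a chain from v
# can enter w a total of delta positions downstream.  Offsets are
# translation-invariant, so one sweep per source vertex suffices.
relaxed_arrival_sets <- function(graph, L) {
  vt <- graph$vertices
  n <- nrow(vt)
  len <- vt$length
  d <- graph$d
  lapply(seq_len(n), function(v) {
    A <- matrix(FALSE, n, L)
    if (len[v] <= L) A[v, 1L] <- TRUE
    for (p in 0:(L - 1L)) {
      done <- logical(n)
      repeat {
        frontier <- which(A[, p + 1L] & !done)
        if (!length(frontier)) break
        done[frontier] <- TRUE
        for (u in frontier) {
          q <- p + d[u, ]
          w <- which(seq_len(n) != u & q + len <= L)
          A[cbind(w, q[w] + 1L)] <- TRUE
        }
      }
    }
    A
  })
}

# Internal layout of the element constraints for the decider: one row per
# element vertex with its vertex index, the absolute window when it is an
# upstream (or unpaired) element, and for downstream partners the upstream
# vertex plus the allowed position gaps.
element_layout <- function(model) {
  vt <- model$graph$vertices
  L <- model$L
  out <- list()
  for (spec in model$elements) {
    k <- which(vt$site_id == spec$id & vt$orientation == "fwd")
    out[[length(out) + 1L]] <-
      list(v = k, lo = spec$start[1], hi = spec$start[2], anchor = NA_integer_)
    if (!is.null(spec$pair)) {
      l <- which(vt$site_id == spec$pair_id & vt$orientation == "fwd")
      len_ref <- if (identical(spec$convention, "printed")) vt$length[l]
                 else vt$length[k]
      gaps <- spec$pair$spacer[1]:spec$pair$spacer[2] + len_ref
      out[[length(out) + 1L]] <-
        list(v = l, lo = spec$start[1] + min(gaps),
             hi = spec$start[2] + max(gaps), anchor = k, gaps = gaps)
    }
  }
  out
}

#' Decide whether the fixed-element constraints admit any packing
#'
#' An exact decision procedure for the feasibility of an element-constrained
#' packing model: anchored depth-first search over placement chains (exact
#' once-only and strand-exclusion bookkeeping, exact spacer linkage), pruned
#' by a sound reachability relaxation of the overlap graph.  Exhausting the
#' search proves infeasibility; any surviving chain is a certificate of
#' feasibility.  The search gives up after `node_budget` nodes and reports
#' `NA` (undecided).
#'
#' @param model A [packing_model][build_model] with fixed elements attached.
#' @param node_budget Maximum number of search nodes before giving up.
#' @return `TRUE` (feasible), `FALSE` (infeasible), or `NA` (undecided).
#' @export
decide_element_feasibility <- function(model, node_budget = 3e5) {
  stopifnot(inherits(model, "packing_model"))
  if (!length(model$elements)) return(TRUE)
  graph <- model$graph
  vt <- graph$vertices
  n <- nrow(vt)
  len <- vt$length
  d <- graph$d
  L <- model$L
  lay <- element_layout(model)
  ne <- length(lay)
  ev <- vapply(lay, `[[`, 0L, "v")
  which_elem <- match(seq_len(n), ev)  # vertex -> element slot or NA
  if (any(vapply(lay, function(e) e$lo > e$hi || e$lo + len[e$v] > L, TRUE))) {
    return(FALSE)
  }
  arr <- relaxed_arrival_sets(graph, L)
  mates <- lapply(seq_len(n), function(v) which(vt$site_id == vt$site_id[v]))

  # exact placement window of element slot j given anchor placements so far
  window_of <- function(j, epos) {
    e <- lay[[j]]
    if (is.na(e$anchor)) return(c(e$lo, e$hi))
    pu <- epos[match(e$anchor, ev)]
    if (is.na(pu)) return(c(e$lo, e$hi))  # upstream not placed yet
    range(pu + e$gaps)
  }

  # sound prune: every pending element must remain reachable from (v, p)
  # under the reuse relaxation, inside its current exact window
  completable <- function(v, p, epos) {
    for (j in which(is.na(epos))) {
      w <- window_of(j, epos)
      if (w[2] < p) return(FALSE)
      qs <- max(w[1], p):w[2]
      if (!any(arr[[v]][lay[[j]]$v, qs - p + 1L])) return(FALSE)
    }
    TRUE
  }

  nodes <- 0L
  used <- logical(n)
  epos <- rep(NA_integer_, ne)
  chain_v <- integer(0)
  chain_p <- integer(0)

  rec <- function(v, p) {
    if (!anyNA(epos)) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > node_budget) {
      stop(structure(list(message = "node budget exhausted", call = NULL),
                     class = c("dp_budget", "error", "condition")))
    }
    q <- p + d[v, ]
    cand <- which(!used & q + len <= L)
    if (!length(cand)) return(FALSE)
    # elements first (they carry the deadlines), then nearest placements
    ord <- order(!(cand %in% ev), q[cand])
    for (w in cand[ord]) {
      j <- which_elem[w]
      if (!is.na(j)) {
        e <- lay[[j]]
        if (!is.na(e$anchor)) {
          # the upstream partner always precedes its downstream element
          # (gaps are strictly positive), so demand it is already placed
          # and enforce the exact spacer linkage
          pu <- epos[match(e$anchor, ev)]
          if (is.na(pu) || !((q[w] - pu) %in% e$gaps)) next
        } else if (q[w] < e$lo || q[w] > e$hi) {
          next
        }
        epos[j] <<- q[w]
      }
      used[mates[[w]]] <<- TRUE
      ok <- completable(w, q[w], epos) && rec(w, q[w])
      used[mates[[w]]] <<- FALSE
      if (!is.na(j)) epos[j] <<- NA_integer_
      if (ok) {
        chain_v <<- c(w, chain_v)
        chain_p <<- c(q[w], chain_p)
        return(TRUE)
      }
    }
    FALSE
  }

  res <- tryCatch({
    found <- FALSE
    # first chain vertex sits at position 0
    for (w in which(len <= L)) {
      j <- which_elem[w]
      if (!is.na(j)) {
        e <- lay[[j]]
        if (!is.na(e$anchor)) next  # a downstream partner cannot open a chain
        if (e$lo > 0L || e$hi < 0L) next
        epos[j] <- 0L
      }
      used[mates[[w]]] <- TRUE
      ok <- completable(w, 0L, epos) && rec(w, 0L)
      used[mates[[w]]] <- FALSE
      if (!is.na(j)) epos[j] <- NA_integer_
      if (ok) {
        chain_v <- c(w, chain_v)
        chain_p <- c(0L, chain_p)
        found <- TRUE
        break
      }
    }
    found
  }, dp_budget = function(e) NA)
  if (isTRUE(res)) {
    witness <- data.frame(vertex = chain_v, position = chain_p)
    verify_element_chain(model, witness)  # errors on any inconsistency
    attr(res, "witness") <- witness
  }
  attr(res, "nodes") <- nodes
  res
}

# Independent validation of a feasibility witness: re-derives every model
# requirement (position arithmetic from the shift metric, budget, once-only
# and strand exclusion, element windows, exact spacers) from scratch.
verify_element_chain <- function(model, witness) {
  vt <- model$graph$vertices
  v <- witness$vertex
  p <- witness$position
  stopifnot(length(v) >= 1, p[1] == 0L)
  if (length(v) > 1) {
    for (t in 2:length(v)) {
      if (p[t] - p[t - 1L] != model$graph$d[v[t - 1L], v[t]]) {
        stop("witness positions break the shift arithmetic", call. = FALSE)
      }
    }
  }
  if (anyDuplicated(vt$site_id[v])) {
    stop("witness reuses a site (or a site with its reverse complement)",
         call. = FALSE)
  }
  last <- length(v)
  if (p[last] + vt$length[v[last]] > model$L) {
    stop("witness exceeds the length budget", call. = FALSE)
  }
  for (e in element_layout(model)) {
    t <- match(e$v, v)
    if (is.na(t)) stop("witness omits a fixed element", call. = FALSE)
    if (is.na(e$anchor)) {
      if (p[t] < e$lo || p[t] > e$hi) {
        stop("witness places an element outside its window", call. = FALSE)
      }
    } else {
      tu <- match(e$anchor, v)
      if (is.na(tu) || !((p[t] - p[tu]) %in% e$gaps)) {
        stop("witness violates a spacer constraint", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
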