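# The packing model is a plain integer linear program kept in a list:
#   var  data.frame(name, type B/I/C, lb, ub, obj)
#   con  list of list(ind, val, sense, rhs, name)
# plus index maps into the variable table.  Index 0 stands for both the
# start and the end vertex, so edge x_0_0 is the start->end edge taken iff
# no site fits within the budget.

#' Build the Orienteering-Problem integer linear program
#'
#' Translates an overlap graph and a length budget into the packing ILP:
#' binary edge variables `x[i,j]` over vertex indices `0..n` (0 = start/end,
#' `x[i,i]` omitted for internal `i`, giving `n^2 + n + 1` binaries), integer
#' Miller-Tucker-Zemlin order variables `u[i]` in `[1, n]`, and the
#' constraints
#' \enumerate{
#'   \item the path leaves the start once and enters the end once,
#'   \item each internal vertex has in-degree and out-degree at most one,
#'   \item flow conservation at every internal vertex,
#'   \item total shift distance along the path at most `L`,
#'   \item MTZ subtour elimination: `u_i - u_j + 1 <= n (1 - x_ij)` for all
#'     ordered internal pairs (`n (n - 1)` rows).
#' }
#' In double-strand mode an exclusion row per site forbids visiting both a
#' site and its own reverse complement.  The objective maximizes the weighted
#' number of edges entering internal vertices (all weights 1 until
#' [set_diversity_weights()] perturbs them).
#'
#' @param graph An [build_graph()] result.
#' @param L Integer length budget in base pairs (`L >= 1`).  A budget smaller
#'   than every site is legal: the start->end edge absorbs it and the optimal
#'   score is 0.
#' @param epsilon Diversity weight increment reserved for
#'   [set_diversity_weights()]; must satisfy `0 < epsilon < 1/n`.  Default
#'   `0.5/n`.
#' @return An object of class `packing_model`.
#' @export
build_model <- function(graph, L, epsilon = NULL) {
  stopifnot(inherits(graph, "overlap_graph"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("'L' must be a positive integer", call. = FALSE)
  vt <- graph$vertices
  n <- nrow(vt)
  if (is.null(epsilon)) epsilon <- 0.5 / n
  if (!(epsilon > 0 && epsilon < 1 / n)) {
    stop("'epsilon' must lie strictly between 0 and 1/n", call. = FALSE)
  }

  # ---- variables ------------------------------------------------------
  # edge variables, i-major; x[i,i] only exists for i = 0
  nv <- n^2 + n + 1L + n            # edges + u
  name <- character(nv); type <- character(nv)
  lb <- numeric(nv); ub <- numeric(nv); obj <- numeric(nv)
  xidx <- matrix(NA_integer_, n + 1L, n + 1L)
  k <- 0L
  for (i in 0:n) {
    for (j in 0:n) {
      if (i == j && i > 0L) next
      k <- k + 1L
      name[k] <- sprintf("x_%d_%d", i, j)
      type[k] <- "B"; lb[k] <- 0; ub[k] <- 1
      obj[k] <- if (j >= 1L) 1 else 0
      xidx[i + 1L, j + 1L] <- k
    }
  }
  n_edge <- k
  uidx <- integer(n)
  for (i in seq_len(n)) {
    k <- k + 1L
    name[k] <- sprintf("u_%d", i)
    type[k] <- "I"; lb[k] <- 1; ub[k] <- n; obj[k] <- 0
    uidx[i] <- k
  }
  var <- data.frame(name = name, type = type, lb = lb, ub = ub, obj = obj,
                    stringsAsFactors = FALSE)

  # ---- constraints ----------------------------------------------------
  dup_sites <- intersect(vt$site_id[vt$orientation == "fwd"],
                         vt$site_id[vt$orientation == "rev"])
  ncon <- 2L + 2L * n + n + 1L + n * (n - 1L) + length(dup_sites)
  con <- vector("list", ncon)
  ci <- 0L
  add <- function(ind, val, sense, rhs, nm) {
    ci <<- ci + 1L
    con[[ci]] <<- list(ind = as.integer(ind), val = as.numeric(val),
                       sense = sense, rhs = rhs, name = nm)
  }
  # 1. leave start once, enter end once
  add(xidx[1L, ], rep(1, n + 1L), "=", 1, "start_out")
  add(xidx[, 1L], rep(1, n + 1L), "=", 1, "end_in")
  # 2. degree bounds on internal vertices
  for (i in seq_len(n)) {
    out <- stats::na.omit(xidx[i + 1L, ])
    add(out, rep(1, length(out)), "<=", 1, sprintf("outdeg_%d", i))
  }
  for (j in seq_len(n)) {
    inn <- stats::na.omit(xidx[, j + 1L])
    add(inn, rep(1, length(inn)), "<=", 1, sprintf("indeg_%d", j))
  }
  # 3. flow conservation
  for (v in seq_len(n)) {
    inn <- stats::na.omit(xidx[, v + 1L])
    out <- stats::na.omit(xidx[v + 1L, ])
    add(c(inn, out), c(rep(1, length(inn)), rep(-1, length(out))), "=", 0,
        sprintf("flow_%d", v))
  }
  # 4. length budget: edges out of internal i cost d[i,j] (end costs len_i)
  bind <- integer(0); bval <- numeric(0)
  for (i in seq_len(n)) {
    for (j in 0:n) {
      if (j == i) next
      dij <- if (j == 0L) vt$length[i] else graph$d[i, j]
      bind <- c(bind, xidx[i + 1L, j + 1L]); bval <- c(bval, dij)
    }
  }
  add(bind, bval, "<=", L, "budget")
  # 5. MTZ subtour elimination
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      add(c(uidx[i], uidx[j], xidx[i + 1L, j + 1L]), c(1, -1, n), "<=", n - 1,
          sprintf("mtz_%d_%d", i, j))
    }
  }
  # strand exclusion: a site and its own reverse complement never co-occur
  for (s in dup_sites) {
    vs <- which(vt$site_id == s)
    inn <- unlist(lapply(vs, function(v) stats::na.omit(xidx[, v + 1L])))
    add(inn, rep(1, length(inn)), "<=", 1, sprintf("exclusion_%s", s))
  }
  stopifnot(ci == ncon)

  structure(
    list(n = n, L = L, strands = graph$strands, graph = graph,
         var = var, con = con,
         xidx = xidx, uidx = uidx, pidx = NULL,
         n_edge_vars = n_edge, n_mtz = n * (n - 1L),
         cvert = rep(1, n), epsilon = epsilon,
         K = NULL, bias = NULL, elements = list()),
    class = "packing_model"
  )
}

#' @export
print.packing_model <- function(x, ...) {
  cat(sprintf(
    "Packing ILP: n = %d internal vertices, L = %d bp (%s strand)\n",
    x$n, x$L, x$strands))
  cat(sprintf("  %d binary edge variables, %d MTZ rows, %d constraints total\n",
              x$n_edge_vars, x$n_mtz, length(x$con)))
  if (!is.null(x$pidx)) cat("  position variables attached\n")
  if (length(x$elements)) {
    cat(sprintf("  %d fixed element(s)\n", length(x$elements)))
  }
  if (!is.null(x$bias)) cat("  side bias active\n")
  invisible(x)
}

# append one constraint (small additions after the bulk build)
con_append <- function(model, ind, val, sense, rhs, nm) {
  model$con[[length(model$con) + 1L]] <-
    list(ind = as.integer(ind), val = as.numeric(val), sense = sense,
         rhs = rhs, name = nm)
  model
}

#' Attach absolute position variables
#'
#' Adds one integer variable per internal vertex with values in `[0, L-1]`,
#' the 0-based start offset of that site in the output sequence, plus linking
#' rows that force `position_j - position_i = d_ij` exactly when the edge
#' `i -> j` is on the path (big-M of `L - 1`; the start vertex has constant
#' position 0, so the first path site starts at offset 0).  Positions of
#' vertices that are not on the path are unconstrained within `[0, L-1]`.
#'
#' Position variables are required by [add_fixed_element()] and
#' [add_side_bias()].
#'
#' @param model A [build_model()] result.
#' @return The model with position variables and linking constraints.
#' @export
attach_positions <- function(model) {
  stopifnot(inherits(model, "packing_model"))
  if (!is.null(model$pidx)) return(model)
  n <- model$n
  L <- model$L
  vt <- model$graph$vertices
  M <- L - 1L
  nv0 <- nrow(model$var)
  pvar <- data.frame(name = sprintf("p_%d", seq_len(n)), type = "I",
                     lb = 0, ub = M, obj = 0, stringsAsFactors = FALSE)
  model$var <- rbind(model$var, pvar)
  pidx <- nv0 + seq_len(n)
  model$pidx <- pidx

  newcon <- vector("list", 2L * n * n)
  ci <- 0L
  for (j in seq_len(n)) {
    for (i in 0:n) {
      if (i == j) next
      x <- model$xidx[i + 1L, j + 1L]
      dij <- if (i == 0L) 0L else model$graph$d[i, j]
      if (i == 0L) {
        # p_j <= d x + M (1 - x)  and  p_j >= d x - M (1 - x), position_0 = 0
        up <- list(ind = c(pidx[j], x), val = c(1, M - dij), sense = "<=",
                   rhs = M, name = sprintf("poslink_up_0_%d", j))
        lo <- list(ind = c(pidx[j], x), val = c(1, -(dij + M)), sense = ">=",
                   rhs = -M, name = sprintf("poslink_lo_0_%d", j))
      } else {
        up <- list(ind = c(pidx[j], pidx[i], x), val = c(1, -1, M - dij),
                   sense = "<=", rhs = M,
                   name = sprintf("poslink_up_%d_%d", i, j))
        lo <- list(ind = c(pidx[j], pidx[i], x), val = c(1, -1, -(dij + M)),
                   sense = ">=", rhs = -M,
                   name = sprintf("poslink_lo_%d_%d", i, j))
      }
      ci <- ci + 1L; newcon[[ci]] <- up
      ci <- ci + 1L; newcon[[ci]] <- lo
    }
  }
  model$con <- c(model$con, newcon[seq_len(ci)])
  model
}

#' Describe a fixed promoter element
#'
#' A fixed element is a sequence (e.g. the sigma factor -35 box `TTGACA`)
#' that every returned array must contain on the forward strand, starting
#' within a window of 0-based positions.  It may carry a paired downstream
#' element (e.g. the -10 box `TATAAT`) separated by a spacer whose length in
#' base pairs is confined to a window.
#'
#' @param seq Element sequence.
#' @param start Integer window `c(alpha, beta)` of allowed 0-based start
#'   positions (inclusive).
#' @param pair Optional `list(seq = , spacer = c(alpha, beta))` describing the
#'   downstream partner and the spacer window in base pairs.
#' @return An object of class `fixed_element`.
#' @examples
#' fixed_element("TTGACA", c(40, 60),
#'               pair = list(seq = "TATAAT", spacer = c(16, 18)))
#' @export
fixed_element <- function(seq, start, pair = NULL) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  start <- as.integer(start)
  if (length(start) != 2L || anyNA(start) || start[1] > start[2] || start[1] < 0L) {
    stop("'start' must be an integer window c(alpha, beta) with 0 <= alpha <= beta",
         call. = FALSE)
  }
  if (!is.null(pair)) {
    if (!is.list(pair) || is.null(pair$seq) || is.null(pair$spacer)) {
      stop("'pair' must be list(seq = , spacer = c(alpha, beta))", call. = FALSE)
    }
    pair$seq <- toupper(as.character(pair$seq))
    pair$spacer <- as.integer(pair$spacer)
    if (length(pair$spacer) != 2L || anyNA(pair$spacer) ||
        pair$spacer[1] > pair$spacer[2]) {
      stop("'spacer' must be an integer window c(alpha, beta)", call. = FALSE)
    }
  }
  structure(list(seq = seq, start = start, pair = pair, id = NULL,
                 pair_id = NULL),
            class = "fixed_element")
}

#' Constrain a fixed element into the model
#'
#' Requires the element's vertex to be entered by the path (`sum_i x_ik >= 1`),
#' confines its position variable to the start window, and, for a paired
#' element, requires the partner too and links the two positions through the
#' spacer window.
#'
#' The printed spacer inequality `alpha <= position_l - length_l - position_k
#' <= beta` measures the spacer with the *downstream* element's length; with
#' positions as start offsets, the biological spacer (gap between the end of
#' the upstream element and the start of the downstream one) is
#' `position_l - position_k - length_k`.  The default `"gap"` convention
#' implements the latter; `"printed"` reproduces the former verbatim.  The
#' two agree whenever both elements have equal length.
#'
#' An element window that cannot be met within `L` surfaces as solver
#' infeasibility, not as a construction error.
#'
#' @param model A [packing_model][build_model] with positions attached, built
#'   from a collection to which the element was added as a fixed site (see
#'   [pack_sites()] which orchestrates this).
#' @param element A [fixed_element()] whose `id`/`pair_id` name fixed sites
#'   of the collection.
#' @param spacer_convention `"gap"` (default) or `"printed"`.
#' @return The constrained model.
#' @export
add_fixed_element <- function(model, element,
                              spacer_convention = c("gap", "printed")) {
  stopifnot(inherits(model, "packing_model"), inherits(element, "fixed_element"))
  spacer_convention <- match.arg(spacer_convention)
  if (is.null(model$pidx)) {
    stop("attach_positions() must be called before adding fixed elements",
         call. = FALSE)
  }
  vt <- model$graph$vertices
  require_vertex <- function(id) {
    k <- which(vt$site_id == id & vt$orientation == "fwd")
    if (length(k) != 1L) {
      stop("fixed element site '", id, "' not found in the graph", call. = FALSE)
    }
    k
  }
  k <- require_vertex(element$id)
  inn <- stats::na.omit(model$xidx[, k + 1L])
  model <- con_append(model, inn, rep(1, length(inn)), ">=", 1,
                      sprintf("require_%s", element$id))
  pk <- model$pidx[k]
  model$var$lb[pk] <- max(model$var$lb[pk], element$start[1])
  model$var$ub[pk] <- min(model$var$ub[pk], element$start[2])
  if (!is.null(element$pair)) {
    l <- require_vertex(element$pair_id)
    inn <- stats::na.omit(model$xidx[, l + 1L])
    model <- con_append(model, inn, rep(1, length(inn)), ">=", 1,
                        sprintf("require_%s", element$pair_id))
    pl <- model$pidx[l]
    len_ref <- if (spacer_convention == "gap") vt$length[k] else vt$length[l]
    sp <- element$pair$spacer
    model <- con_append(model, c(pl, pk), c(1, -1), ">=", sp[1] + len_ref,
                        sprintf("spacer_lo_%s", element$id))
    model <- con_append(model, c(pl, pk), c(1, -1), "<=", sp[2] + len_ref,
                        sprintf("spacer_hi_%s", element$id))
  }
  element$convention <- spacer_convention
  model$elements <- c(model$elements, list(element))
  model
}

#' Bias sites towards the upstream or downstream end of the array
#'
#' Adds the term `-position_i / K` (upstream preference) or
#' `+position_i / K` (downstream preference) to the objective for every
#' vertex of each biased site.  `K` is chosen large enough that the summed
#' perturbation stays within `[-0.5, 0.5]`, so solutions with different
#' numbers of binding sites can never be reordered; the default
#' `K = 2 n (L - 1)` guarantees this since at most `n` sites contribute at
#' most `(L - 1)/K` each.
#'
#' @param model A [packing_model][build_model] with positions attached.
#' @param preferences Named character vector mapping site ids to
#'   `"upstream"` or `"downstream"`.
#' @param K Positive scale constant; default `2 * n * (L - 1)` (doubled again
#'   by [pack_sites()] when diversity weights are active at the same time, so
#'   the two perturbation budgets still sum below 0.5).
#' @return The model with the biased objective.
#' @export
add_side_bias <- function(model, preferences, K = NULL) {
  stopifnot(inherits(model, "packing_model"))
  if (length(preferences) == 0L) return(model)
  if (is.null(model$pidx)) {
    stop("attach_positions() must be called before adding side biases",
         call. = FALSE)
  }
  prefs <- as.character(preferences)
  if (is.null(names(preferences)) || !all(prefs %in% c("upstream", "downstream"))) {
    stop("'preferences' must be a named vector of \"upstream\"/\"downstream\"",
         call. = FALSE)
  }
  vt <- model$graph$vertices
  unknown <- setdiff(names(preferences), vt$site_id)
  if (length(unknown)) {
    stop("unknown site id(s) in bias: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(K)) K <- 2 * model$n * max(model$L - 1L, 1L)
  if (K <= 0) stop("'K' must be positive", call. = FALSE)
  for (s in names(preferences)) {
    sgn <- if (prefs[[match(s, names(preferences))]] == "upstream") -1 else 1
    for (v in which(vt$site_id == s)) {
      model$var$obj[model$pidx[v]] <- model$var$obj[model$pidx[v]] + sgn / K
    }
  }
  model$K <- K
  model$bias <- preferences
  model
}

#' Reweight the objective towards under-represented sites
#'
#' Implements the diversity-driven enumeration rule: given usage counts of
#' each site across previously returned solutions, every edge entering a
#' vertex whose origin site is used *strictly less* than the mean usage gets
#' objective weight `1 + epsilon`; all other entering edges keep weight 1.
#' Any `0 < epsilon < 1/n` keeps the perturbation too small to ever prefer a
#' solution with fewer sites over one with more.
#'
#' @param model A [packing_model][build_model].
#' @param counts Named numeric vector of usage counts covering every
#'   (non-fixed) site of the collection.
#' @param epsilon Weight increment; defaults to the value fixed at model
#'   creation (`0.5/n`).
#' @return The model with updated objective weights.
#' @export
set_diversity_weights <- function(model, counts, epsilon = NULL) {
  stopifnot(inherits(model, "packing_model"))
  if (is.null(epsilon)) epsilon <- model$epsilon
  if (!(epsilon > 0 && epsilon < 1 / model$n)) {
    stop("'epsilon' must lie strictly between 0 and 1/n", call. = FALSE)
  }
  vt <- model$graph$vertices
  ids <- unique(vt$site_id[!vt$fixed])
  if (!all(ids %in% names(counts))) {
    stop("'counts' must cover every site of the collection", call. = FALSE)
  }
  counts <- counts[ids]
  mean_count <- sum(counts) / length(counts)
  below <- names(counts)[counts < mean_count - 1e-12]
  model$cvert <- ifelse(!vt$fixed & vt$site_id %in% below, 1 + epsilon, 1)
  # refresh entering-edge objective coefficients
  for (j in seq_len(model$n)) {
    rows <- stats::na.omit(model$xidx[, j + 1L])
    model$var$obj[rows] <- model$cvert[j]
  }
  model$epsilon_active <- epsilon
  model
}

# Pin the (unweighted) base score of any solution to S.
add_score_pin <- function(model, S) {
  ind <- integer(0)
  for (j in seq_len(model$n)) {
    ind <- c(ind, stats::na.omit(model$xidx[, j + 1L]))
  }
  con_append(model, ind, rep(1, length(ind)), "=", S, "score_pin")
}

# Exclude one exact active-edge set (no-good cut).
add_no_good_cut <- function(model, active_rows, tag = "") {
  con_append(model, active_rows, rep(1, length(active_rows)), "<=",
             length(active_rows) - 1, paste0("nogood", tag))
}
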