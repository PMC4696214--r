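# Network-analytic summaries of a transition matrix: most probable
# neighbours/paths, flow thresholds, betweenness on -log-transformed
# weights, and per-state probability summaries.

# adjacency list of positive transitions j -> i (prob M[i, j]) with
# costs -log p; zero entries are absent edges, not infinite costs
edge_lists <- function(P) {
  n <- ncol(P)
  if (is(P, "sparseMatrix")) {
    Pc <- methods::as(P, "CsparseMatrix")
    lapply(seq_len(n), function(j) {
      idx <- (Pc@p[j] + 1L):Pc@p[j + 1L]
      if (Pc@p[j + 1L] == Pc@p[j]) return(list(to = integer(0), p = numeric(0)))
      keep <- Pc@x[idx] > 0
      list(to = Pc@i[idx][keep] + 1L, p = Pc@x[idx][keep])
    })
  } else {
    lapply(seq_len(n), function(j) {
      to <- which(P[, j] > 0)
      list(to = to, p = P[to, j])
    })
  }
}

# Dijkstra over costs -log p from one source.  Deterministic:
# equal-cost frontier nodes are popped in ascending index order and an
# equal-cost relaxation keeps the earlier-indexed predecessor.
dijkstra_neglog <- function(adj, source, allow_self = FALSE) {
  n <- length(adj)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  done <- logical(n)
  dist[source] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]        # which.min returns first = smallest index
    done[u] <- TRUE
    e <- adj[[u]]
    for (k in seq_along(e$to)) {
      v <- e$to[k]
      if (v == u) next                 # self-loops never shorten a path
      nd <- dist[u] - log(e$p[k])
      if (nd < dist[v] && !done[v]) {
        dist[v] <- nd
        pred[v] <- u
      }
    }
  }
  list(dist = dist, pred = pred)
}

reconstruct_path <- function(pred, source, target) {
  path <- target
  while (path[1] != source) {
    p <- pred[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

#' Most probable neighbours of every state
#'
#' For each source state `j`, the destination states `i` maximizing
#' `M[i, j]` (the one-step analog of a nearest neighbour); all tied
#' maxima are reported.  Also returns the in-degree of each state in the
#' resulting directed graph, i.e. for how many other states it is the
#' most likely next step.
#'
#' @param m A `transition_matrix`, bare matrix or sparse `Matrix`.
#' @param include_self Include the diagonal when taking the maximum
#'   (default `TRUE`); with `FALSE`, near-absorbing states point to
#'   their best non-self destination.
#' @return List with `edges` (data frame `from`, `to`, `probability`,
#'   `rule`) and `in_degree` (integer per state).
#' @export
most_probable_neighbors <- function(m, include_self = TRUE) {
  P <- tm_storage(m)
  n <- ncol(P)
  from <- integer(0); to <- integer(0); pr <- numeric(0)
  for (j in seq_len(n)) {
    col <- as.numeric(P[, j])
    if (!include_self) col[j] <- -Inf
    mx <- max(col)
    i <- which(col == mx)
    from <- c(from, rep.int(j, length(i)))
    to <- c(to, i)
    pr <- c(pr, rep.int(mx, length(i)))
  }
  edges <- data.frame(from = from, to = to, probability = pr,
                      rule = "most_probable_neighbor")
  in_degree <- tabulate(edges$to, nbins = n)
  list(edges = edges, in_degree = in_degree)
}

#' Most probable path between two states
#'
#' The state sequence maximizing the product of one-step transition
#' probabilities, found by Dijkstra's algorithm on edge costs
#' `-log M[i, j]` (all non-negative).  Self-loops are never interior
#' steps.
#'
#' @inheritParams most_probable_neighbors
#' @param source,target State indices (1-based).
#' @return List with `path` (state index sequence) and `probability`
#'   (product of its edge probabilities; 1 when `source == target`).
#' @export
most_probable_path <- function(m, source, target) {
  P <- tm_storage(m)
  n <- ncol(P)
  source <- as.integer(source); target <- as.integer(target)
  stopifnot(source >= 1, source <= n, target >= 1, target <= n)
  if (source == target) return(list(path = source, probability = 1))
  adj <- edge_lists(P)
  d <- dijkstra_neglog(adj, source)
  path <- if (is.finite(d$dist[target]))
    reconstruct_path(d$pred, source, target) else NULL
  if (is.null(path))
    stop(sprintf("state %d is unreachable from state %d (no positive-probability path)",
                 target, source))
  probs <- vapply(seq_len(length(path) - 1),
                  function(k) as.numeric(P[path[k + 1], path[k]]), numeric(1))
  list(path = path, probability = prod(probs), edge_probabilities = probs)
}

#' Flow threshold: bottleneck probability of the most probable path
#'
#' The smallest one-step probability along the most probable path
#' between two states.  Filtering the matrix at this threshold (see
#' [filter_edges()]) keeps every edge of that path while excluding rarer
#' transitions.
#'
#' @inheritParams most_probable_path
#' @return The minimum edge probability along the path.
#' @export
bottleneck_threshold <- function(m, source, target) {
  mp <- most_probable_path(m, source, target)
  if (length(mp$path) == 1) return(1)
  min(mp$edge_probabilities)
}

#' Edges at or above a probability threshold
#'
#' Support function for percolation-style displays: all directed edges
#' whose transition probability is at least `threshold`.
#'
#' @inheritParams most_probable_neighbors
#' @param threshold Minimum probability.
#' @return Data frame `from`, `to`, `probability`, `rule`.
#' @export
filter_edges <- function(m, threshold) {
  P <- tm_storage(m)
  if (!is(P, "Matrix")) P <- Matrix::Matrix(P, sparse = TRUE)
  Pt <- methods::as(methods::as(P, "CsparseMatrix"), "TsparseMatrix")
  keep <- Pt@x >= threshold & Pt@x > 0
  df <- data.frame(from = Pt@j[keep] + 1L, to = Pt@i[keep] + 1L,
                   probability = Pt@x[keep],
                   rule = sprintf("probability >= %g", threshold))
  df[order(df$from, df$to), , drop = FALSE]
}

#' Betweenness under most probable paths
#'
#' For every ordered pair of distinct states, the most probable path is
#' computed (Dijkstra on `-log` weights, deterministic tie-breaking) and
#' each state counts the paths passing through it as an interior node.
#' High counts mark frequent transient states.
#'
#' @inheritParams most_probable_neighbors
#' @return Integer vector of path counts per state.
#' @export
betweenness_paths <- function(m) {
  P <- tm_storage(m)
  n <- ncol(P)
  adj <- edge_lists(P)
  counts <- integer(n)
  unreachable <- character(0)
  for (s in seq_len(n)) {
    d <- dijkstra_neglog(adj, s)
    for (t in seq_len(n)) {
      if (t == s) next
      if (!is.finite(d$dist[t])) {
        unreachable <- c(unreachable, sprintf("%d->%d", s, t))
        next
      }
      path <- reconstruct_path(d$pred, s, t)
      if (length(path) > 2) {
        interior <- path[-c(1, length(path))]
        counts[interior] <- counts[interior] + 1L
      }
    }
  }
  if (length(unreachable) > 0)
    stop("graph is disconnected; unreachable pairs: ",
         paste(head(unreachable, 10), collapse = ", "),
         if (length(unreachable) > 10) " ..." else "")
  counts
}

#' Per-state probability summaries
#'
#' Transient and limiting per-state statistics: `p_stay(i) = M[i,i]`
#' (stickiness), `p_out(i) = 1 - M[i,i]`, `p_in(i)` — probability to
#' arrive at `i` when all previous states are equally likely (off-diagonal
#' row sum over `|S| - 1`), and with a limiting distribution `v`:
#' `p_in_inf(i)` — arrival probability in an infinite run (off-diagonal
#' row entries weighted by `v`), and `p_inf(i) = v_i` itself.
#'
#' @inheritParams most_probable_neighbors
#' @param v Optional `limiting_distribution` (or bare probability
#'   vector); required for `p_in_inf` / `p_inf`.
#' @return Data frame with one row per state.
#' @export
node_probability_summary <- function(m, v = NULL) {
  P <- tm_storage(m)
  n <- ncol(P)
  dg <- if (is(P, "Matrix")) Matrix::diag(P) else diag(P)
  out <- data.frame(state = seq_len(n),
                    p_stay = dg,
                    p_out = 1 - dg,
                    p_in = (as.numeric(if (is(P, "Matrix")) Matrix::rowSums(P)
                                       else rowSums(P)) - dg) / (n - 1))
  if (!is.null(v)) {
    vv <- if (inherits(v, "limiting_distribution")) v$v else v
    out$p_in_inf <- as.numeric(P %*% vv) - dg * vv
    out$p_inf <- vv
  }
  out
}

#' Extract one column: arrival probabilities from a given state
#'
#' `p(i | j) = M[i, j]` for all `i`; the distribution of destinations of
#' a transition starting at state `j`.
#'
#' @inheritParams most_probable_neighbors
#' @param j Source state index.
#' @return Numeric probability vector of length `|S|`.
#' @export
arrival_probabilities <- function(m, j) {
  as.numeric(tm_storage(m)[, j])
}
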