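# Independent oracles and generators used across the suite.

# random strictly positive column-stochastic matrix
random_stochastic <- function(n, seed) {
  set.seed(seed)
  P <- matrix(runif(n * n, min = 0.01, max = 1), n, n)
  sweep(P, 2, colSums(P), "/")
}

# plain power iteration, independent of the package's solver
power_iteration_oracle <- function(P, steps = 1e4) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(steps)) {
    v <- as.numeric(P %*% v)
    v <- v / sum(v)
  }
  v
}

# exhaustive enumeration of all simple paths src -> dst (column
# convention: edge j -> i has probability P[i, j]); returns the maximal
# product and every path attaining it
brute_force_best_path <- function(P, src, dst) {
  n <- nrow(P)
  best <- list(prob = -Inf, paths = list())
  recurse <- function(path, prob) {
    last <- path[length(path)]
    if (last == dst) {
      if (prob > best$prob + 1e-15) {
        best$prob <<- prob
        best$paths <<- list(path)
      } else if (abs(prob - best$prob) <= 1e-15) {
        best$paths <<- c(best$paths, list(path))
      }
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% path) next
      p <- P[nxt, last]
      if (p > 0) recurse(c(path, nxt), prob * p)
    }
  }
  recurse(src, 1)
  best
}

# betweenness by brute force: count, per node, the best paths (one per
# ordered pair, first-found tie winner matching ascending enumeration)
brute_force_betweenness <- function(P) {
  n <- nrow(P)
  counts <- integer(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    b <- brute_force_best_path(P, s, t)
    path <- b$paths[[1]]
    if (length(path) > 2) {
      interior <- path[-c(1, length(path))]
      counts[interior] <- counts[interior] + 1L
    }
  }
  counts
}

# hand-rolled six-step column approximation, written independently as a
# direct transcription of the scheme (kept naive on purpose)
hand_approximate_column <- function(col, i, s) {
  n <- length(col)
  rank_order <- order(-col, seq_len(n))
  csum <- 0
  r <- 0
  for (k in seq_len(n)) {
    csum <- csum + col[rank_order[k]]
    if (csum >= s) { r <- k; break }
  }
  if (r == 0) r <- n
  if (r < 2) r <- 2
  while (r < n && col[rank_order[r + 1]] == col[rank_order[r]]) r <- r + 1
  protected <- ((c(i - 1, i, i + 1) - 1) %% n) + 1
  out <- col
  if (r < n) {
    for (k in (r + 1):n) {
      row <- rank_order[k]
      if (!(row %in% protected)) out[row] <- 0
    }
  }
  out / sum(out)
}
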