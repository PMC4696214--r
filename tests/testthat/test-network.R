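test_that("most probable neighbours are the per-column argmax, ties included", {
  P <- cbind(c(0.1, 0.6, 0.3), c(0.45, 0.45, 0.1), c(0.2, 0.2, 0.6))
  mpn <- most_probable_neighbors(P)
  expect_identical(mpn$edges$to[mpn$edges$from == 1], 2L)
  expect_identical(sort(mpn$edges$to[mpn$edges$from == 2]), c(1L, 2L))
  expect_identical(mpn$in_degree, c(1L, 2L, 1L))
  # self-exclusion picks the best off-diagonal destination
  mpn2 <- most_probable_neighbors(P, include_self = FALSE)
  expect_identical(mpn2$edges$to[mpn2$edges$from == 3], c(1L, 2L))
})

test_that("model neighbours equal an independent per-column argmax oracle", {
  m <- build_transition_matrix(model_params(10, 1e-6, 0))
  mpn <- most_probable_neighbors(m)
  for (j in seq_len(ncol(m$P))) {
    expected <- which(m$P[, j] == max(m$P[, j]))
    expect_identical(sort(mpn$edges$to[mpn$edges$from == j]),
                     as.integer(expected))
  }
})

test_that("most probable path maximizes the probability product", {
  # three-state chain: stepping 1->2->3 (0.25) beats jumping 1->3 (0.2)
  P <- cbind(c(0.3, 0.5, 0.2), c(0, 0.5, 0.5), c(0, 0, 1))
  mp <- most_probable_path(P, 1, 3)
  expect_identical(mp$path, c(1L, 2L, 3L))
  expect_equal(mp$probability, 0.25)
  expect_equal(bottleneck_threshold(P, 1, 3), 0.5)
  expect_identical(most_probable_path(P, 2, 2),
                   list(path = 2L, probability = 1))
  # unreachable: no edge leads back from fixation
  expect_error(most_probable_path(P, 3, 1), "unreachable")
})

test_that("paths agree with exhaustive simple-path enumeration on small matrices", {
  for (seed in 1:20) {
    P <- random_stochastic(5, seed)
    for (pair in list(c(1, 5), c(2, 4), c(5, 1))) {
      mp <- most_probable_path(P, pair[1], pair[2])
      best <- brute_force_best_path(P, pair[1], pair[2])
      expect_equal(mp$probability, best$prob, tolerance = 1e-12)
      # negative-log costs are consistent with the returned probability
      expect_equal(sum(-log(mp$edge_probabilities)),
                   -log(mp$probability), tolerance = 1e-10)
    }
  }
})

test_that("paths on the N = 5 model agree with an independent Dijkstra", {
  m <- build_transition_matrix(model_params(5, 1e-6, 0))
  P <- as.matrix(m$P)
  g <- igraph::graph_from_adjacency_matrix(t(P), mode = "directed",
                                           weighted = TRUE)
  igraph::E(g)$weight <- -log(igraph::E(g)$weight)
  d_oracle <- igraph::distances(g, v = 1, mode = "out",
                                algorithm = "dijkstra")
  for (target in c(6, 15, 21)) {
    mp <- most_probable_path(m, 1, target)
    expect_equal(-log(mp$probability), d_oracle[1, target],
                 tolerance = 1e-10)
  }
  # fixation-to-fixation crosses the interior instead of hugging the base
  mp <- most_probable_path(m, 1, 21)
  het <- m$space$states[mp$path, 2]
  expect_gt(max(het), 0)
})

test_that("betweenness counts match brute-force path enumeration", {
  # two-state chains have no interior nodes
  expect_identical(betweenness_paths(matrix(c(0.5, 0.5, 0.5, 0.5), 2)),
                   c(0L, 0L))
  # all routes forced through the middle state
  P <- cbind(c(0.5, 0.5, 0), c(0.25, 0.5, 0.25), c(0, 0.5, 0.5))
  expect_identical(betweenness_paths(P), c(0L, 2L, 0L))
  for (seed in 1:100) {
    P <- random_stochastic(5, seed)
    expect_identical(betweenness_paths(P), brute_force_betweenness(P))
  }
})

test_that("disconnected graphs raise an error listing unreachable pairs", {
  P <- diag(2)
  expect_error(betweenness_paths(P), "unreachable")
})

test_that("flow-threshold filtering keeps every edge of the best path", {
  P <- random_stochastic(6, 3)
  mp <- most_probable_path(P, 1, 6)
  thr <- bottleneck_threshold(P, 1, 6)
  edges <- filter_edges(P, thr)
  for (k in seq_len(length(mp$path) - 1)) {
    hit <- edges$from == mp$path[k] & edges$to == mp$path[k + 1]
    expect_true(any(hit))
  }
  expect_true(all(edges$probability >= thr))
})

test_that("node probability summaries satisfy their identities", {
  P <- random_stochastic(6, 11)
  v <- dominant_eigenvector(P)
  st <- node_probability_summary(P, v = v)
  expect_equal(st$p_stay + st$p_out, rep(1, 6))
  expect_equal(st$p_stay, diag(P))
  expect_equal(st$p_inf, v$v)
  # p_in_inf(i) = sum_{j != i} M[i,j] v_j
  manual <- vapply(1:6, function(i) sum(P[i, -i] * v$v[-i]), numeric(1))
  expect_equal(st$p_in_inf, manual, tolerance = 1e-12)
  # uniform matrix: every state equally reachable
  U <- matrix(1 / 4, 4, 4)
  expect_equal(node_probability_summary(U)$p_in, rep(0.25, 4))
  # degenerate weighting: v concentrated on state j* reads off column j*
  v1 <- c(0, 1, 0, 0, 0, 0)
  st1 <- node_probability_summary(P, v = v1)
  expect_equal(st1$p_in_inf[-2], P[-2, 2])
  expect_equal(arrival_probabilities(P, 2), P[, 2])
})

test_that("high in-degree states sit on or near Hardy-Weinberg proportions", {
  for (N in c(5, 20)) {
    m <- build_transition_matrix(model_params(N, 1e-6, 0))
    deg <- most_probable_neighbors(m)$in_degree
    best <- which(deg == max(deg))
    freqs <- m$space$states[best, , drop = FALSE] / N
    nu_a <- freqs[, 1] + freqs[, 2] / 2
    hw_het <- 2 * nu_a * (1 - nu_a)
    expect_true(all(abs(freqs[, 2] - hw_het) <= 1 / N + 1e-12))
  }
})
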