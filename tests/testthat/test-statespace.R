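test_that("genotype counts follow the per-locus multiset product", {
  expect_identical(genotype_count(2, 2), 3)
  expect_identical(genotype_count(4, 2), 5)
  expect_identical(genotype_count(2, c(2, 2)), 9)
  expect_identical(genotype_count(2, 4), 10)
  expect_identical(genotype_count(2, c(2, 9)), 3 * 45)
  # haploid single locus: one genotype per allele
  for (k in c(1, 3, 7)) expect_identical(genotype_count(1, k), k)
  expect_error(genotype_count(0, 2), "ploidy")
  expect_error(genotype_count(2, c(2, 0)), "allele")
})

test_that("state-space cardinality is the multiset coefficient C(N+g-1, N)", {
  expect_identical(state_count(20, 3), 231)
  expect_identical(state_count(100, 3), 5151)
  expect_identical(state_count(5, 3), 21)
  expect_identical(state_count(20, 5), 10626)
  for (g in 2:5) expect_identical(state_count(1, g), as.numeric(g))
  expect_error(state_count(-1, 3), "non-negative")
})

test_that("cardinality values beyond 2^53 are exact in big-integer form", {
  # C(100, 20), frozen from exact integer arithmetic (independently
  # cross-checked against Python's math.comb)
  expect_identical(state_count(80, 21, as = "character"),
                   "535983370403809682970")
  expect_identical(state_count(20, 100, as = "character"),
                   "24551856075980529765105")
  expect_error(state_count(20, 100), "character")
  # numeric and character routes agree where both are exact
  expect_identical(state_count(1000, 3, as = "character"), "501501")
  expect_identical(state_count(1000, 3), 501501)
  expect_identical(state_count(500, 3), 125751)
})

test_that("cardinality grows exactly by (N+g)/(N+1) per added individual", {
  for (g in c(3, 5, 10)) {
    for (N in 1:50) {
      lhs <- state_count(N + 1, g) * (N + 1)
      rhs <- state_count(N, g) * (N + g)
      expect_identical(lhs, rhs)
    }
  }
})

test_that("state enumeration is complete, ordered and indexable", {
  expect_identical(length(enumerate_states(1)), 3L)
  expect_identical(length(enumerate_states(2)), 6L)
  expect_identical(length(enumerate_states(5)), 21L)
  for (N in c(1, 3, 10, 30, 50))
    expect_identical(length(enumerate_states(N)), as.integer(state_count(N, 3)))
  sp <- enumerate_states(4)
  expect_identical(unname(sp$states[1, ]), c(4L, 0L, 0L))
  expect_identical(unname(sp$states[nrow(sp$states), ]), c(0L, 0L, 4L))
  expect_true(all(rowSums(sp$states) == 4L))
  # descending lexicographic in (n_aa, n_aA)
  key <- sp$states[, 1] * 5 + sp$states[, 2]
  expect_true(all(diff(key) < 0 | diff(sp$states[, 1]) < 0))
  # index is a bijection consistent with the ordering
  expect_identical(state_index(sp, sp$states), seq_len(15L))
  expect_error(enumerate_states(0), "positive")
})

test_that("swap-paired ordering is a permutation of the same states", {
  sp <- enumerate_states(6)
  alt <- enumerate_states(6, order = "swap_paired")
  expect_identical(nrow(alt$states), nrow(sp$states))
  expect_identical(sort(state_index(sp, alt$states)), seq_len(length(sp)))
  # consecutive off-axis states are allele-swap partners
  expect_identical(unname(alt$states[2, ]), rev(unname(alt$states[1, ])))
})

test_that("allele swap is an involution fixing the symmetry axis", {
  for (N in c(1:6, 10, 20, 30)) {
    sp <- enumerate_states(N)
    sig <- allele_swap_permutation(sp)
    expect_identical(sig[sig], seq_along(sig))
    expect_identical(sig[1], length(sp))   # (N,0,0) <-> (0,0,N)
    axis <- sp$states[, 1] == sp$states[, 3]
    expect_identical(which(axis), which(sig == seq_along(sig)))
  }
})

test_that("de Finetti coordinates hit the stated corners and stay in the triangle", {
  N <- 7
  xy <- definetti_coords(rbind(c(N, 0, 0), c(0, 0, N), c(0, N, 0)), N = N)
  expect_equal(unname(xy[1, ]), c(0, 0))
  expect_equal(unname(xy[2, ]), c(1, 0))
  expect_equal(unname(xy[3, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(definetti_coords(c(1, 2, 1), N = 4)[1, ]),
               c(0.5, 0.4330127), tolerance = 1e-7)
  for (N in c(2, 5, 12)) {
    xy <- definetti_coords(enumerate_states(N))
    expect_true(all(xy[, 2] >= -1e-12))
    expect_true(all(xy[, 2] <= sqrt(3) * xy[, 1] + 1e-12))          # left edge
    expect_true(all(xy[, 2] <= sqrt(3) * (1 - xy[, 1]) + 1e-12))    # right edge
  }
  # corner relabeling permutes the image, not the triangle
  xy2 <- definetti_coords(c(3, 0, 0), N = 3, corners = c("AA", "aA", "aa"))
  expect_equal(unname(xy2[1, ]), c(1, 0))
})

test_that("state spaces serialize to TSV with coordinates", {
  sp <- enumerate_states(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_statespace(sp, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(df), 10L)
  expect_named(df, c("index", "n_aa", "n_aA", "n_AA", "x", "y"))
  expect_equal(df$x, definetti_coords(sp)[, 1])
})
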