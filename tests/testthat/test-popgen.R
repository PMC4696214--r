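# helper: assemble a fis_distribution by hand for divergence tests
manual_fis <- function(values, mass, undefined = 0) {
  structure(list(values = values, mass = mass,
                 keys = as.character(values), undefined_mass = undefined),
            class = "fis_distribution")
}

test_that("F_IS takes its textbook values", {
  expect_equal(fis(c(1, 2, 1), N = 4), 0)          # Hardy-Weinberg
  expect_equal(fis(c(0, 4, 0), N = 4), -1)         # all heterozygotes
  expect_equal(fis(c(2, 0, 2), N = 4), 1)          # no heterozygotes
  expect_true(is.na(fis(c(4, 0, 0), N = 4)))       # monomorphic: undefined
  expect_true(is.na(fis(c(0, 0, 4), N = 4)))
  sp <- enumerate_states(6)
  f <- fis(sp)
  expect_identical(length(f), length(sp))
  # allele swap leaves F_IS unchanged
  sig <- allele_swap_permutation(sp)
  expect_identical(f[sig], f)
})

test_that("limiting F_IS distributions aggregate eigenvector mass exactly", {
  sp <- enumerate_states(4)
  v <- numeric(length(sp))
  v[state_index(sp, c(1, 2, 1))] <- 1
  fd <- fis_distribution(v, sp)
  expect_identical(fd$values, 0)
  expect_identical(fd$mass, 1)
  expect_identical(fd$undefined_mass, 0)
  # mass splits across classes and the monomorphic remainder
  v2 <- numeric(length(sp))
  v2[state_index(sp, c(4, 0, 0))] <- 0.5
  v2[state_index(sp, c(0, 4, 0))] <- 0.3
  v2[state_index(sp, c(1, 2, 1))] <- 0.2
  fd2 <- fis_distribution(v2, sp)
  expect_equal(fd2$undefined_mass, 0.5)
  expect_equal(fd2$values, c(-1, 0))
  expect_equal(fd2$mass, c(0.3, 0.2))
  expect_equal(sum(fd2$mass) + fd2$undefined_mass, 1)
})

test_that("states with equal exact F_IS fall into one class", {
  sp <- enumerate_states(8)
  fd <- fis_distribution(rep(1 / length(sp), length(sp)), sp)
  f <- fis(sp)
  expect_identical(length(fd$values), length(unique(f[!is.na(f)])))
  expect_false(any(duplicated(fd$values)))
})

test_that("fixation dominates the limiting F_IS distribution at small mu", {
  m <- build_transition_matrix(model_params(5, 1e-6, 0))
  v <- dominant_eigenvector(m)
  fd <- fis_distribution(v)
  expect_gt(fd$undefined_mass, 0.5)
  # allele-swap permutation of the eigenvector leaves the distribution intact
  sig <- allele_swap_permutation(m$space)
  fd2 <- fis_distribution(v$v[sig], m$space)
  expect_equal(fd2$values, fd$values)
  expect_equal(fd2$mass, fd$mass, tolerance = 1e-12)
})

test_that("divergences vanish iff the distributions coincide", {
  f <- manual_fis(c(-1, 0, 1), c(0.2, 0.5, 0.3))
  for (meth in c("total_distance", "kl", "power_divergence", "ks"))
    expect_equal(fis_divergence(f, f, meth), 0)
  g <- manual_fis(c(-1, 0, 1), c(0.3, 0.4, 0.3))
  for (meth in c("total_distance", "kl", "power_divergence", "ks"))
    expect_gt(fis_divergence(f, g, meth), 0)
})

test_that("divergences take their hand-computed values", {
  f <- manual_fis(c(0, 1), c(1, 0))
  g <- manual_fis(c(0, 1), c(0, 1))
  expect_equal(fis_divergence(f, g, "total_distance"), 2)
  expect_equal(fis_divergence(f, g, "ks"), 1)
  f2 <- manual_fis(c(0, 1), c(0.8, 0.2))
  g2 <- manual_fis(c(0, 1), c(0.5, 0.5))
  expect_equal(fis_divergence(f2, g2, "kl"),
               0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  expect_equal(fis_divergence(f2, g2, "kl"), 0.1927448, tolerance = 1e-6)
  lam <- 2 / 3
  expect_equal(fis_divergence(f2, g2, "power_divergence"),
               2 / (lam * (lam + 1)) *
                 (0.8 * (1.6^lam - 1) + 0.2 * (0.4^lam - 1)),
               tolerance = 1e-12)
})

test_that("distributions align on the union of classes before comparison", {
  f <- manual_fis(c(0), c(1))
  g <- manual_fis(c(0, 0.5), c(0.6, 0.4))
  expect_equal(fis_divergence(f, g, "total_distance"), 0.8)
  expect_equal(fis_divergence(f, g, "ks"), 0.4)
  # classes absent on one side are omitted from KL (infinite terms)
  expect_equal(fis_divergence(f, g, "kl"), log(1 / 0.6), tolerance = 1e-12)
})

test_that("divergence bounds hold on random distributions", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:8, 1)
    vals <- sort(runif(k, -1, 1))
    a <- runif(k); a <- a / sum(a)
    b <- runif(k); b <- b / sum(b)
    f <- manual_fis(vals, a); g <- manual_fis(vals, b)
    td <- fis_divergence(f, g, "total_distance")
    ks <- fis_divergence(f, g, "ks")
    expect_gte(td, 0); expect_lte(td, 2)
    expect_gte(ks, 0); expect_lte(ks, 1)
    expect_gte(fis_divergence(f, g, "kl"), -1e-12)
    expect_lte(ks, td / 2 + 1e-12)   # KS never exceeds half the L1 distance
  }
})

test_that("unnormalized distributions are rejected", {
  bad <- manual_fis(c(0, 1), c(0.5, 0.3))
  ok <- manual_fis(c(0, 1), c(0.5, 0.5))
  expect_error(fis_divergence(bad, ok), "not 1")
})

test_that("the G-test matches direct evaluation and omits impossible classes", {
  gt <- g_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
  gt2 <- g_test(c(0.6, 0.4), c(0.5, 0.5), n_eff = 100)
  expect_equal(gt2$statistic,
               200 * (0.6 * log(1.2) + 0.4 * log(0.8)), tolerance = 1e-12)
  expect_equal(gt2$statistic, 4.027103, tolerance = 1e-6)
  expect_equal(gt2$df, 1)
  expect_equal(gt2$p_value, pchisq(gt2$statistic, 1, lower.tail = FALSE))
  # a class with g = 0 < f is dropped and counted
  gt3 <- g_test(c(0.5, 0.3, 0.2), c(0.6, 0.4, 0), n_eff = 10)
  expect_identical(gt3$omitted, 1L)
  expect_equal(gt3$df, 1)
  expect_error(g_test(c(1, 0), c(0.5, 0.5)), "fewer than 2")
  expect_error(g_test(c(0.6, 0.3), c(0.5, 0.5)), "sum to 1")
})

test_that("approximation distorts the limiting F_IS distribution only slightly", {
  # absolute orig-vs-approx distance is small and shrinks as s -> 1
  m <- build_transition_matrix(model_params(20, 1e-6, 0.1))
  fd0 <- fis_distribution(dominant_eigenvector(m))
  d <- vapply(c(0.9, 0.99), function(s) {
    fis_divergence(fd0,
                   fis_distribution(dominant_eigenvector(approximate_matrix(m, s))),
                   "total_distance")
  }, numeric(1))
  expect_lt(d[1], 0.01)
  expect_lt(d[2], d[1])
})

test_that("F_IS distributions round-trip through TSV", {
  m <- build_transition_matrix(model_params(6, 1e-5, 0.3))
  fd <- fis_distribution(dominant_eigenvector(m))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fis_distribution(fd, path)
  fd2 <- read_fis_distribution(path)
  expect_equal(fd2$values, fd$values)
  expect_equal(fd2$mass, fd$mass)
  expect_equal(fd2$undefined_mass, fd$undefined_mass)
  expect_identical(fd2$keys, fd$keys)
})
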