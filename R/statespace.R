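# State space of the one-locus / two-allele genotype-frequency model:
# all assignments of N diploid individuals to the genotypes (aa, aA, AA).

# ---- exact integer arithmetic -------------------------------------------
# Cardinalities reach ~1e21 (beyond 2^53), so binomials are computed with
# a tiny base-1e7 limb representation: only multiplication and exact
# division by small integers are needed for C(n, k) built up term by term.

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x < BIG_BASE)
  as.numeric(x)
}

big_mul_small <- function(limbs, m) {
  # limbs little-endian, m < ~9e6 so limb*m stays exact in doubles
  prod <- limbs * m
  carry <- 0
  out <- numeric(0)
  i <- 1
  while (i <= length(prod) || carry > 0) {
    v <- carry + if (i <= length(prod)) prod[i] else 0
    out[i] <- v %% BIG_BASE
    carry <- (v - out[i]) / BIG_BASE
    i <- i + 1
  }
  out
}

big_div_small <- function(limbs, d) {
  # exact division, most-significant limb first
  out <- numeric(length(limbs))
  rem <- 0
  for (i in rev(seq_along(limbs))) {
    v <- rem * BIG_BASE + limbs[i]
    out[i] <- v %/% d
    rem <- v %% d
  }
  if (rem != 0) stop("internal error: inexact big-integer division")
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_to_string <- function(limbs) {
  digs <- vapply(rev(limbs), function(l) sprintf("%07.0f", l), character(1))
  s <- sub("^0+", "", paste0(digs, collapse = ""))
  if (s == "") "0" else s
}

big_to_numeric <- function(limbs) {
  sum(limbs * BIG_BASE^(seq_along(limbs) - 1))
}

# exact C(n, k) as a limb vector; k reduced to min(k, n - k)
big_binom <- function(n, k) {
  if (k < 0 || k > n) return(big_from_int(0))
  k <- min(k, n - k)
  acc <- big_from_int(1)
  for (i in seq_len(k)) {
    acc <- big_mul_small(acc, n - k + i)
    acc <- big_div_small(acc, i)
  }
  acc
}

# ---- cardinalities -------------------------------------------------------

#' Number of possible genotypes for a genomic configuration
#'
#' Computes the number of distinct genotypes `g` of an organism of ploidy
#' `P` at `L` (partially linked) loci carrying `A[i]` alleles each, as the
#' product of per-locus multiset coefficients `C(A[i] + P - 1, P)`.
#'
#' @param P Ploidy level (positive integer).
#' @param A Integer vector of allele counts per locus (all positive).
#' @param as Return type: `"numeric"` (default; errors if the exact value
#'   exceeds 2^53) or `"character"` (exact decimal digits, any size).
#' @return Number of genotypes, exact.
#' @examples
#' genotype_count(2, 2)       # biallelic diploid locus: 3
#' genotype_count(2, c(2, 2)) # two biallelic loci: 9
#' @export
genotype_count <- function(P, A, as = c("numeric", "character")) {
  as <- match.arg(as)
  if (length(P) != 1 || is.na(P) || P < 1 || P != round(P))
    stop("ploidy P must be a positive integer")
  if (length(A) < 1 || anyNA(A) || any(A < 1) || any(A != round(A)))
    stop("allele counts A must all be positive integers")
  acc <- big_from_int(1)
  for (a in A) acc <- big_mul_big(acc, big_binom(a + P - 1, P))
  big_return(acc, as, "genotype count")
}

big_mul_big <- function(a, b) {
  out <- big_from_int(0)
  shift <- numeric(0)
  for (i in seq_along(b)) {
    term <- big_mul_small(a, b[i])
    term <- c(shift, term)
    out <- big_add(out, term)
    shift <- c(shift, 0)
  }
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  out <- numeric(0)
  i <- 1
  while (i <= n || carry > 0) {
    v <- carry + if (i <= n) s[i] else 0
    out[i] <- v %% BIG_BASE
    carry <- (v - out[i]) / BIG_BASE
    i <- i + 1
  }
  out
}

big_return <- function(limbs, as, what) {
  if (as == "character") return(big_to_string(limbs))
  v <- big_to_numeric(limbs)
  if (v > 2^53)
    stop(what, " exceeds 2^53; request as = \"character\" for exact digits")
  v
}

#' Cardinality of the genotype-count state space
#'
#' For `N` individuals distributed over `g` genotypes the number of states
#' is the multiset coefficient `C(N + g - 1, N)`, computed in exact
#' integer arithmetic (values in realistic configurations reach ~1e21).
#'
#' @param N Population size (non-negative integer).
#' @param g Number of genotypes (positive integer), e.g. from
#'   [genotype_count()].
#' @inheritParams genotype_count
#' @return The number of states, exact.
#' @examples
#' state_count(20, 3)   # 231
#' state_count(100, 3)  # 5151
#' @export
state_count <- function(N, g, as = c("numeric", "character")) {
  as <- match.arg(as)
  if (length(N) != 1 || is.na(N) || N < 0 || N != round(N))
    stop("population size N must be a non-negative integer")
  if (length(g) != 1 || is.na(g) || g < 1 || g != round(g))
    stop("genotype count g must be a positive integer")
  big_return(big_binom(N + g - 1, min(N, g - 1)), as, "state count")
}

# ---- enumeration ---------------------------------------------------------

#' Enumerate the genotype-count state space
#'
#' Lists every assignment of `N` individuals to the three genotypes
#' (aa, aA, AA).  Canonical order is lexicographically descending in
#' `(n_aa, n_aA)`: `(N,0,0)` first, `(0,0,N)` last.  The alternative
#' `"swap_paired"` order interleaves each state with its allele-swapped
#' partner (states on the symmetry axis appear once), which makes the
#' partial symmetry of transition matrices visible in heat maps.
#'
#' @param N Population size (positive integer).
#' @param order `"lexicographic"` (default) or `"swap_paired"`.
#' @return A `state_space` object: list with `N`, integer matrix `states`
#'   (columns `n_aa`, `n_aA`, `n_AA`), and the order label.
#' @examples
#' enumerate_states(2)
#' @export
enumerate_states <- function(N, order = c("lexicographic", "swap_paired")) {
  order <- match.arg(order)
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N))
    stop("population size N must be a positive integer")
  n_aa <- rep(N:0, times = N - (N:0) + 1)
  n_aA <- unlist(lapply(N:0, function(a) seq(N - a, 0)), use.names = FALSE)
  states <- cbind(n_aa = n_aa, n_aA = n_aA, n_AA = N - n_aa - n_aA)
  storage.mode(states) <- "integer"
  sp <- structure(list(N = as.integer(N), states = states,
                       order = "lexicographic"),
                  class = "state_space")
  if (order == "swap_paired") {
    sigma <- allele_swap_permutation(sp)
    seen <- logical(nrow(states))
    idx <- integer(0)
    for (i in seq_len(nrow(states))) {
      if (seen[i]) next
      idx <- c(idx, i)
      seen[i] <- TRUE
      if (sigma[i] != i && !seen[sigma[i]]) {
        idx <- c(idx, sigma[i])
        seen[sigma[i]] <- TRUE
      }
    }
    sp$states <- states[idx, , drop = FALSE]
    sp$order <- "swap_paired"
  }
  sp
}

#' @export
print.state_space <- function(x, ...) {
  cat("Genotype-count state space: N =", x$N,
      "|S| =", nrow(x$states), paste0("(", x$order, " order)"), "\n")
  print(head(x$states, 4))
  if (nrow(x$states) > 4) cat("... ", nrow(x$states) - 4, " more states\n")
  invisible(x)
}

#' @export
length.state_space <- function(x) nrow(x$states)

#' Index of states within a state space
#'
#' @param space A `state_space`.
#' @param states Integer matrix (or length-3 vector) of genotype counts.
#' @return Integer indices into `space$states` (1-based).
#' @export
state_index <- function(space, states) {
  stopifnot(inherits(space, "state_space"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  key <- function(m) m[, 1] * (space$N + 1L) + m[, 2]
  match(key(states), key(space$states))
}

#' Allele-swap permutation of state indices
#'
#' Symmetric mutation makes the model invariant under renaming the
#' alleles; this returns the permutation sigma with
#' `sigma(index(n_aa, n_aA, n_AA)) = index(n_AA, n_aA, n_aa)`.
#' It is an involution.
#'
#' @param space A `state_space`.
#' @return Integer vector: `sigma[i]` is the index of the swapped state.
#' @export
allele_swap_permutation <- function(space) {
  stopifnot(inherits(space, "state_space"))
  swapped <- space$states[, c(3, 2, 1), drop = FALSE]
  colnames(swapped) <- colnames(space$states)
  state_index(space, swapped)
}

#' De Finetti (ternary) coordinates of genotype states
#'
#' Maps genotype counts to the ternary plot used in population genetics:
#' `x = nu_AA + nu_aA / 2`, `y = sqrt(3)/2 * nu_aA` with frequencies
#' `nu = counts / N`.  Corners: all-aa at (0,0), all-AA at (1,0),
#' all-heterozygote at the apex (1/2, sqrt(3)/2).  The corner assignment
#' can be permuted via `corners`.
#'
#' @param states Integer matrix of genotype counts (columns aa, aA, AA)
#'   or a `state_space`.
#' @param N Population size; taken from the `state_space` if given one.
#' @param corners Permutation of `c("aa", "aA", "AA")` assigning the
#'   (left, apex, right) corners; default `c("aa", "aA", "AA")`.
#' @return Two-column numeric matrix `x`, `y`.
#' @examples
#' definetti_coords(rbind(c(4, 0, 0), c(1, 2, 1)), N = 4)
#' @export
definetti_coords <- function(states, N = NULL,
                             corners = c("aa", "aA", "AA")) {
  if (inherits(states, "state_space")) {
    N <- states$N
    states <- states$states
  }
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (is.null(N)) stop("N is required when states is a bare matrix")
  if (!setequal(corners, c("aa", "aA", "AA")))
    stop("corners must be a permutation of c(\"aa\", \"aA\", \"AA\")")
  perm <- match(corners, c("aa", "aA", "AA"))
  nu <- states[, perm, drop = FALSE] / N
  cbind(x = nu[, 3] + nu[, 2] / 2, y = sqrt(3) / 2 * nu[, 2])
}

#' Write a state space (with de Finetti coordinates) to TSV
#'
#' Columns: `index`, `n_aa`, `n_aA`, `n_AA`, `x`, `y`.
#'
#' @param space A `state_space`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_statespace <- function(space, path) {
  stopifnot(inherits(space, "state_space"))
  xy <- definetti_coords(space)
  df <- data.frame(index = seq_len(nrow(space$states)), space$states, xy)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
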