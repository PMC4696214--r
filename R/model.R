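# Genotype-frequency Wright-Fisher model with partial clonality:
# one locus, two alleles, fixed population size N, symmetric per-allele
# mutation rate mu, clonality rate c.  Columns of the transition matrix
# are multinomial distributions over offspring genotype counts.

#' Model parameters for the partially clonal genotype-frequency chain
#'
#' @param N Population size (positive integer).
#' @param mu Symmetric per-allele mutation probability per generation,
#'   in \[0, 0.5\].
#' @param c Probability that an offspring is produced clonally (uniform
#'   copy of one parent), in \[0, 1\]; `1 - c` is the probability of
#'   sexual reproduction by random union of gametes.
#' @param clonal_mutation Apply per-allele mutation to clonally produced
#'   offspring as well (default `TRUE`; with `FALSE` clones are exact
#'   copies and the matrix loses its everywhere-positive density at
#'   `c = 1`).
#' @return A `model_params` list.
#' @export
model_params <- function(N, mu, c, clonal_mutation = TRUE) {
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  if (length(mu) != 1 || is.na(mu) || mu < 0 || mu > 0.5)
    stop("mu must lie in [0, 0.5]")
  if (length(c) != 1 || is.na(c) || c < 0 || c > 1)
    stop("c must lie in [0, 1]")
  structure(list(N = as.integer(N), mu = mu, c = c,
                 clonal_mutation = isTRUE(clonal_mutation)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model parameters: N = %d, mu = %g, c = %g%s\n",
              x$N, x$mu, x$c,
              if (x$clonal_mutation) "" else " (no mutation in clones)"))
  invisible(x)
}

# per-genotype two-allele mutation kernel: column = parent genotype,
# row = offspring genotype after independent per-allele mutation
mutation_kernel <- function(mu) {
  p <- 1 - mu
  matrix(c(p^2,      2 * mu * p,    mu^2,
           mu * p,   p^2 + mu^2,    mu * p,
           mu^2,     2 * mu * p,    p^2),
         nrow = 3, byrow = FALSE,
         dimnames = list(c("aa", "aA", "AA"), c("aa", "aA", "AA")))
}

#' Single-offspring genotype distribution given a parental state
#'
#' Mixture of the two reproductive pathways: with probability `c` the
#' offspring is a uniform copy of one parent (per-allele mutation applied
#' unless disabled), with probability `1 - c` it is the random union of
#' two mutated gametes drawn at the parental allele frequency.
#'
#' @param state Genotype counts `(n_aa, n_aA, n_AA)` (vector or matrix,
#'   one state per row).
#' @param params A [model_params()] object.
#' @return Probability vector (or matrix, one row per state) over the
#'   offspring genotypes `(aa, aA, AA)`; rows sum to 1.
#' @export
offspring_distribution <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  one <- is.null(dim(state))
  if (one) state <- matrix(state, nrow = 1)
  if (any(rowSums(state) != params$N) || any(state < 0))
    stop("state counts must be non-negative and sum to N")
  N <- params$N; mu <- params$mu; cc <- params$c
  nu_a <- (state[, 1] + state[, 2] / 2) / N
  nu_m <- nu_a * (1 - mu) + (1 - nu_a) * mu     # mutated gamete frequency
  sexual <- cbind(nu_m^2, 2 * nu_m * (1 - nu_m), (1 - nu_m)^2)
  freqs <- state / N
  clonal <- if (params$clonal_mutation) {
    freqs %*% t(mutation_kernel(mu))
  } else {
    freqs
  }
  pi <- cc * clonal + (1 - cc) * sexual
  colnames(pi) <- c("aa", "aA", "AA")
  if (one) pi[1, ] else pi
}

# log multinomial pmf of every state in `space` given genotype probs pi;
# handles zero probabilities exactly (0 * log 0 = 0, positive count on a
# zero-probability genotype gives probability 0)
multinomial_column <- function(space, pi, log_norm) {
  st <- space$states
  if (all(pi > 0)) {
    lp <- log(pi)
    return(exp(log_norm + st %*% lp))
  }
  lp <- ifelse(pi > 0, log(pi), 0)
  contrib <- st %*% lp
  impossible <- st[, pi == 0, drop = FALSE]
  bad <- rowSums(impossible) > 0
  out <- exp(log_norm + contrib)
  out[bad] <- 0
  out
}

#' Build the dense transition matrix of the model
#'
#' Column `j` holds the multinomial distribution of drawing `N`
#' independent offspring from [offspring_distribution()] of state `j`
#' (left-stochastic convention: entry `(i, j)` is the probability of a
#' one-step transition from state `j` to state `i`).  For `mu > 0` every
#' entry is strictly positive, so the chain is irreducible and aperiodic.
#'
#' @param params A [model_params()] object.
#' @param space Optional pre-built `state_space` (must match `params$N`).
#' @param max_states Capacity guard: error if the state space exceeds
#'   this many states (the dense matrix needs `|S|^2` doubles).
#' @return A [transition_matrix()] with dense storage bound to its
#'   state space and parameters.
#' @examples
#' m <- build_transition_matrix(model_params(5, 1e-6, 0))
#' dim(m)
#' @export
build_transition_matrix <- function(params, space = NULL,
                                    max_states = 6000L) {
  stopifnot(inherits(params, "model_params"))
  ns <- state_count(params$N, 3)
  if (ns > max_states)
    stop(sprintf(paste0("state space has |S| = %d states; dense ",
                        "materialization above max_states = %d refused ",
                        "(raise max_states or use the column generator)"),
                 ns, max_states))
  if (is.null(space)) space <- enumerate_states(params$N)
  if (space$N != params$N) stop("space and params disagree on N")
  n <- length(space)
  Pi <- offspring_distribution(space$states, params)   # n x 3
  log_norm <- lgamma(params$N + 1) - rowSums(lgamma(space$states + 1))
  if (all(Pi > 0)) {
    M <- exp(outer(log_norm, rep(1, n)) + space$states %*% t(log(Pi)))
  } else {
    M <- matrix(0, n, n)
    for (j in seq_len(n))
      M[, j] <- multinomial_column(space, Pi[j, ], log_norm)
  }
  transition_matrix(M, space = space, params = params)
}

#' One column of the model transition matrix, computed on demand
#'
#' Returns a generator closure so that sparse approximation and
#' column-wise summaries can run without ever materializing the dense
#' matrix.
#'
#' @inheritParams build_transition_matrix
#' @return A function `f(j)` returning column `j` (length `|S|`), with
#'   attributes `n` (dimension) and `space`.
#' @export
transition_column_generator <- function(params, space = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(space)) space <- enumerate_states(params$N)
  if (space$N != params$N) stop("space and params disagree on N")
  log_norm <- lgamma(params$N + 1) - rowSums(lgamma(space$states + 1))
  f <- function(j) {
    pi <- offspring_distribution(space$states[j, ], params)
    multinomial_column(space, pi, log_norm)[, 1]
  }
  attr(f, "n") <- length(space)
  attr(f, "space") <- space
  f
}
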