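# Light container binding a column-stochastic matrix (dense base matrix
# or sparse Matrix) to its state space and, when known, model parameters.

#' Transition matrix container
#'
#' Wraps a square column-stochastic matrix (left-stochastic convention:
#' entry `(i, j)` is the one-step probability from state `j` to state
#' `i`) together with the `state_space` it is bound to.  Storage may be a
#' dense base matrix or a sparse `Matrix::dgCMatrix`; all package
#' operations accept either, or a bare matrix.
#'
#' @param P Square numeric matrix (base or `Matrix` sparse) with columns
#'   summing to 1.
#' @param space Optional `state_space` with `length(space) == nrow(P)`.
#' @param params Optional `model_params`.
#' @param validate Check column sums (tolerance 1e-6) and entry range.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(P, space = NULL, params = NULL,
                              validate = TRUE) {
  if (inherits(P, "transition_matrix")) return(P)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (!is.null(space) && length(space) != nrow(P))
    stop("state space size does not match matrix dimension")
  if (validate) {
    cs <- colsums_any(P)
    if (any(abs(cs - 1) > 1e-6))
      stop(sprintf("column %d sums to %.8g, not 1",
                   which.max(abs(cs - 1)), cs[which.max(abs(cs - 1))]))
    if (min_any(P) < 0) stop("transition probabilities must be >= 0")
  }
  structure(list(P = P, space = space, params = params),
            class = "transition_matrix")
}

# accept transition_matrix, base matrix or Matrix; return the storage
tm_storage <- function(m) {
  if (inherits(m, "transition_matrix")) m$P else m
}

tm_space <- function(m) {
  if (inherits(m, "transition_matrix")) m$space else NULL
}

colsums_any <- function(P) {
  if (is(P, "Matrix")) Matrix::colSums(P) else colSums(P)
}

min_any <- function(P) {
  if (is(P, "sparseMatrix")) {
    x <- P@x
    if (length(x) < length(P)) min(0, x) else min(x)
  } else min(P)
}

#' @export
dim.transition_matrix <- function(x) dim(x$P)

#' @export
print.transition_matrix <- function(x, ...) {
  kind <- if (is(x$P, "sparseMatrix")) "sparse" else "dense"
  cat(sprintf("Column-stochastic transition matrix: %d x %d (%s, density %.4g)\n",
              nrow(x$P), ncol(x$P), kind, matrix_density(x)))
  if (!is.null(x$params))
    cat(sprintf("  model: N = %d, mu = %g, c = %g\n",
                x$params$N, x$params$mu, x$params$c))
  invisible(x)
}

#' @export
as.matrix.transition_matrix <- function(x, ...) as.matrix(x$P)
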