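# Limiting distribution (dominant right eigenvector for eigenvalue 1)
# and expected first-passage times of a column-stochastic matrix.

#' Limiting distribution of an irreducible, aperiodic chain
#'
#' Computes the normalized right eigenvector `v` with `M v = v`.  The
#' default method solves the singular system directly: `(M - I) v = 0`
#' with one equation replaced by the normalization `sum(v) = 1`, using a
#' dense or sparse LU factorization — robust even when the spectral gap
#' is tiny (mutation rates ~1e-6 put the subdominant eigenvalue within
#' ~1e-6 of 1, where power iteration stalls).  `method = "power"`
#' provides plain power iteration for cross-checking on well-gapped
#' matrices.
#'
#' @param m A `transition_matrix`, bare matrix or sparse `Matrix`
#'   (column-stochastic, irreducible, aperiodic).
#' @param method `"solve"` (default) or `"power"`.
#' @param tol Residual tolerance: the returned vector must satisfy
#'   `sum(abs(M v - v)) < tol` or an error is raised.
#' @param max_iter Iteration cap for `method = "power"`.
#' @return A `limiting_distribution`: list with `v` (non-negative,
#'   sums to 1), `residual`, and the bound `space` if any.
#' @examples
#' dominant_eigenvector(matrix(c(0.9, 0.1, 0.1, 0.9), 2))$v
#' @export
dominant_eigenvector <- function(m, method = c("solve", "power"),
                                 tol = 1e-8, max_iter = 1e6) {
  method <- match.arg(method)
  P <- tm_storage(m)
  n <- nrow(P)
  if (method == "solve") {
    if (is(P, "sparseMatrix")) {
      # ground state n (set v_n = 1, solve for the rest): avoids the
      # dense normalization row that would destroy sparsity in the LU
      A <- methods::as(P, "CsparseMatrix") - Matrix::Diagonal(n)
      w <- tryCatch(as.numeric(Matrix::solve(A[-n, -n, drop = FALSE],
                                             -A[-n, n, drop = TRUE])),
                    error = function(e)
                      stop("stationary solve failed (reducible matrix?): ",
                           conditionMessage(e), call. = FALSE))
      v <- c(w, 1)
    } else {
      A <- P - diag(n)
      A[n, ] <- 1
      v <- tryCatch(solve(A, c(rep(0, n - 1), 1)),
                    error = function(e)
                      stop("stationary solve failed (reducible matrix?): ",
                           conditionMessage(e), call. = FALSE))
    }
    v[v < 0 & v > -1e-12] <- 0
    if (any(v < 0))
      stop("stationary solve produced negative probabilities; ",
           "matrix may be reducible or ill-conditioned")
    v <- v / sum(v)
  } else {
    v <- rep(1 / n, n)
    delta <- Inf
    it <- 0
    while (it < max_iter) {
      w <- as.numeric(P %*% v)
      w <- w / sum(w)
      delta <- sum(abs(w - v))
      v <- w
      it <- it + 1
      if (delta < 1e-13) break
      if (sum(abs(as.numeric(P %*% v) - v)) < 1e-10) break
    }
    if (it >= max_iter && delta >= 1e-13)
      stop(sprintf("power iteration did not converge in %g iterations (last L1 change %.3g)",
                   max_iter, delta))
  }
  residual <- sum(abs(as.numeric(P %*% v) - v))
  if (residual >= tol)
    stop(sprintf("eigenvector residual %.3g exceeds tolerance %.3g; matrix may be reducible",
                 residual, tol))
  structure(list(v = v, residual = residual, space = tm_space(m)),
            class = "limiting_distribution")
}

#' @export
print.limiting_distribution <- function(x, ...) {
  cat(sprintf("Limiting distribution over %d states (residual %.3g)\n",
              length(x$v), x$residual))
  invisible(x)
}

#' Expected first-passage times to a target state set
#'
#' The target states are made absorbing; with `M'` the sub-matrix of
#' transition probabilities among non-target states (column convention),
#' the expected hitting times solve `t (I - M') = 1`.  Target states
#' have time exactly 0.
#'
#' @param m A `transition_matrix`, bare matrix or sparse `Matrix`.
#' @param targets Non-empty integer vector of target state indices
#'   (1-based).
#' @return Numeric vector of expected times (generations) per state;
#'   0 at the targets, strictly positive elsewhere.
#' @examples
#' M <- matrix(c(0.8, 0.2, 0, 1), 2)   # state 1 exits to 2 w.p. 0.2
#' first_passage_times(M, targets = 2) # c(5, 0)
#' @export
first_passage_times <- function(m, targets) {
  P <- tm_storage(m)
  n <- nrow(P)
  targets <- unique(as.integer(targets))
  if (length(targets) < 1) stop("targets must be non-empty")
  if (any(targets < 1 | targets > n)) stop("target index out of range")
  rest <- setdiff(seq_len(n), targets)
  out <- numeric(n)
  if (length(rest) > 0) {
    Mp <- P[rest, rest, drop = FALSE]
    # t (I - M') = 1  <=>  (I - M')^T t^T = 1
    A <- if (is(Mp, "Matrix")) {
      Matrix::t(Matrix::Diagonal(length(rest)) - Mp)
    } else {
      t(diag(length(rest)) - Mp)
    }
    tt <- tryCatch(as.numeric(Matrix::solve(A, rep(1, length(rest)))),
                   error = function(e)
                     stop("first-passage solve failed; targets may be unreachable from some states: ",
                          conditionMessage(e), call. = FALSE))
    if (any(!is.finite(tt)) || any(tt <= 0))
      stop("non-positive or non-finite first-passage times; targets unreachable from some states")
    out[rest] <- tt
  }
  out
}
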