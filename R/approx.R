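# Structure-preserving sparse approximation of a column-stochastic
# matrix.  Per column: keep the largest entries until their cumulative
# mass reaches the threshold s (at least the two largest; all ties at
# the cutoff), zero the rest except the main diagonal and the wrapped
# first sub-/super-diagonal (which preserve aperiodicity and
# irreducibility), then rescale the column to sum to 1.

# rows forced to survive in column i of an n x n matrix (1-based):
# {(i-1), i, (i+1)} with wrap-around, i.e. a Hamiltonian cycle.
wrap_diagonal_rows <- function(i, n) {
  unique(((c(i - 1L, i, i + 1L) - 1L) %% n) + 1L)
}

#' Sparse-approximate one matrix column
#'
#' Implements the six-step per-column scheme: (1) rank entries by
#' decreasing value, ties broken by ascending row index; (2) find the
#' minimal rank `r` whose cumulative sum reaches the threshold `s`;
#' (3) `r = max(2, r)` — always keep the two largest values; (4) extend
#' `r` over any run of values tied with the `r`-th; (5) zero all entries
#' ranked beyond `r` except rows `(i-1, i, i+1) mod n` (never creating
#' entries that were zero originally); (6) rescale the kept entries to
#' sum to 1.
#'
#' @param column Numeric probability vector (sums to 1 within 1e-9).
#' @param i Column index (1-based) within the n x n matrix.
#' @param s Threshold in \[0, 1\]: minimal probability mass retained per
#'   column before rescaling.
#' @param n Matrix dimension; defaults to `length(column)`.
#' @return List with `rows` (kept row indices, ascending), `values`
#'   (rescaled probabilities) and `discarded` (probability mass removed
#'   before rescaling, always `<= 1 - s`).
#' @examples
#' approximate_column(c(0.5, 0.3, 0.15, 0.04, 0.01), i = 1, s = 0.9)
#' @export
approximate_column <- function(column, i, s, n = length(column)) {
  if (length(s) != 1 || is.na(s) || s < 0 || s > 1)
    stop("threshold s must lie in [0, 1]")
  if (abs(sum(column) - 1) > 1e-9)
    stop(sprintf("column %d is not normalized (sum = %.10g)", i, sum(column)))
  if (length(column) != n) stop("column length does not match n")
  ord <- order(-column, seq_along(column))          # step 1 (stable)
  cum <- cumsum(column[ord])
  r <- which(cum >= s)[1L]                          # step 2
  if (is.na(r)) r <- n
  r <- max(2L, r)                                   # step 3
  while (r < n && column[ord[r + 1L]] == column[ord[r]]) r <- r + 1L  # step 4
  keep <- logical(n)
  keep[ord[seq_len(min(r, n))]] <- TRUE
  keep[wrap_diagonal_rows(i, n)] <- TRUE            # step 5
  discarded <- sum(column[!keep])
  vals <- column[keep]
  rows <- which(keep)
  nz <- vals > 0                                    # zero originals stay absent
  rows <- rows[nz]; vals <- vals[nz]
  list(rows = rows, values = vals / sum(vals),      # step 6
       discarded = discarded)
}

#' Sparse-approximate a whole transition matrix
#'
#' Applies [approximate_column()] to every column, assembling a sparse
#' column-compressed matrix.  The result is column-stochastic, keeps
#' every original diagonal entry (aperiodicity) and the wrapped first
#' sub-/super-diagonal cycle (irreducibility), while one-step
#' transitions between all states are deliberately given up.  When given
#' a column generator (see [transition_column_generator()]) the dense
#' matrix is never stored; peak memory is the sparse result plus one
#' column.
#'
#' @param m A `transition_matrix`, bare matrix, or column-generator
#'   function with attribute `n`.
#' @param s Threshold in \[0, 1\].
#' @return A `transition_matrix` with sparse storage; element `report`
#'   holds the threshold, per-column discarded mass, and the resulting
#'   density.
#' @export
approximate_matrix <- function(m, s) {
  if (is.function(m)) {
    n <- attr(m, "n")
    if (is.null(n)) stop("column generator must carry attribute 'n'")
    space <- attr(m, "space")
    get_col <- m
  } else {
    P <- tm_storage(m)
    n <- ncol(P)
    space <- tm_space(m)
    get_col <- function(j) as.numeric(P[, j])
  }
  rows_l <- vector("list", n)
  vals_l <- vector("list", n)
  discarded <- numeric(n)
  for (j in seq_len(n)) {
    ap <- tryCatch(approximate_column(get_col(j), j, s, n),
                   error = function(e)
                     stop(sprintf("column %d: %s", j, conditionMessage(e)),
                          call. = FALSE))
    rows_l[[j]] <- ap$rows
    vals_l[[j]] <- ap$values
    discarded[j] <- ap$discarded
  }
  nnz <- lengths(rows_l)
  S <- Matrix::sparseMatrix(i = unlist(rows_l),
                            j = rep.int(seq_len(n), nnz),
                            x = unlist(vals_l), dims = c(n, n))
  out <- transition_matrix(S, space = space,
                           params = if (inherits(m, "transition_matrix"))
                             m$params else NULL)
  out$report <- list(s = s, discarded = discarded,
                     density = length(S@x) / (as.numeric(n)^2))
  out
}

#' Report of a sparse approximation
#'
#' @param m A `transition_matrix` produced by [approximate_matrix()].
#' @return List with threshold `s`, per-column `discarded` mass (before
#'   rescaling) and the resulting `density`.
#' @export
approx_report <- function(m) {
  if (!inherits(m, "transition_matrix") || is.null(m$report))
    stop("no approximation report attached; was this matrix produced by approximate_matrix()?")
  m$report
}

#' Density of a matrix
#'
#' Fraction of entries stored as nonzero: `nnz / n^2`.
#'
#' @param m A `transition_matrix`, bare matrix or `Matrix`.
#' @return Density in \[0, 1\].
#' @export
matrix_density <- function(m) {
  P <- tm_storage(m)
  nnz <- if (is(P, "sparseMatrix")) length(P@x) else sum(P != 0)
  nnz / (as.numeric(nrow(P)) * ncol(P))
}

#' Strong connectivity of the transition graph
#'
#' A transition matrix is irreducible iff the directed graph of its
#' positive entries is strongly connected.
#'
#' @param m A `transition_matrix`, bare matrix or `Matrix`.
#' @return `TRUE`/`FALSE`.
#' @export
is_strongly_connected <- function(m) {
  P <- tm_storage(m)
  g <- igraph::graph_from_adjacency_matrix(Matrix::t(methods::as(P, "CsparseMatrix")) != 0,
                                           mode = "directed")
  igraph::is_connected(g, mode = "strong")
}
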