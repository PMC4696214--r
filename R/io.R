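# Matrix/vector I/O and deterministic fixtures.  Sparse interchange is
# Matrix Market coordinate format (1-based on disk); dense small
# matrices and all vectors/tables are TSV.

#' Read a column-stochastic matrix
#'
#' Formats: `"matrix-market"` (`.mtx`, via `Matrix::readMM`; coordinate
#' indices are 1-based on disk) or `"tsv"` (dense, no header, tab
#' separated).  Column sums are validated: deviations beyond 1e-6 warn,
#' beyond 1e-3 are an error.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"matrix-market"` or `"tsv"`.
#' @return A `transition_matrix` (no state space bound).
#' @export
read_matrix <- function(path, format = c("auto", "matrix-market", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "matrix-market" else "tsv"
  P <- if (format == "matrix-market") {
    methods::as(Matrix::readMM(path), "CsparseMatrix")
  } else {
    as.matrix(read.table(path, sep = "\t", header = FALSE))
  }
  dimnames(P) <- NULL
  if (nrow(P) != ncol(P))
    stop(sprintf("matrix in %s is %d x %d, not square", path,
                 nrow(P), ncol(P)))
  cs <- colsums_any(P)
  worst <- max(abs(cs - 1))
  if (worst > 1e-3)
    stop(sprintf("column %d of %s sums to %.6g; not a stochastic matrix",
                 which.max(abs(cs - 1)), path, cs[which.max(abs(cs - 1))]))
  if (worst > 1e-6)
    warning(sprintf("column sums of %s deviate from 1 by up to %.3g",
                    path, worst))
  transition_matrix(P, validate = FALSE)
}

#' Write a matrix to disk
#'
#' Sparse storage goes to Matrix Market coordinate format; dense
#' storage to TSV (or Matrix Market if the path ends in `.mtx`).
#'
#' @param m A `transition_matrix`, bare matrix or `Matrix`.
#' @param path Output file (`.mtx` or `.tsv`).
#' @return The path, invisibly.
#' @export
write_matrix <- function(m, path) {
  P <- tm_storage(m)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(P, sparse = TRUE),
                                "CsparseMatrix"), path)
  } else {
    write.table(as.matrix(P), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write / read a per-state vector as TSV
#'
#' Columns `state` (1-based index) and `value`.
#'
#' @param v Numeric vector, or `limiting_distribution`.
#' @param path File path.
#' @return `write_vector_tsv`: the path invisibly; `read_vector_tsv`:
#'   the numeric vector.
#' @export
write_vector_tsv <- function(v, path) {
  if (inherits(v, "limiting_distribution")) v <- v$v
  write.table(data.frame(state = seq_along(v), value = v), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vector_tsv
#' @export
read_vector_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  df$value[order(df$state)]
}

#' Deterministic test matrices
#'
#' Small column-stochastic matrices used across the test suite and the
#' examples: `"toy3"` / `"toy5"` are fixed 3x3 / 5x5 chains, `"random"`
#' is a seeded strictly positive column-normalized matrix, `"model"` is
#' the genotype-frequency model matrix for small `N`.
#'
#' @param kind One of `"toy3"`, `"toy5"`, `"random"`, `"model"`.
#' @param seed Seed for `"random"`.
#' @param n Dimension for `"random"`.
#' @param N,mu,c Model parameters for `"model"`.
#' @return A `transition_matrix`.
#' @export
make_fixture <- function(kind = c("toy3", "toy5", "random", "model"),
                         seed = 1, n = 5, N = 5, mu = 1e-6, c = 0) {
  kind <- match.arg(kind)
  switch(kind,
    toy3 = transition_matrix(matrix(c(0.8, 0.15, 0.05,
                                      0.10, 0.70, 0.20,
                                      0.05, 0.25, 0.70), 3)),
    toy5 = transition_matrix(matrix(c(0.50, 0.30, 0.15, 0.04, 0.01,
                                      0.20, 0.40, 0.25, 0.10, 0.05,
                                      0.05, 0.25, 0.40, 0.25, 0.05,
                                      0.05, 0.10, 0.25, 0.40, 0.20,
                                      0.01, 0.04, 0.15, 0.30, 0.50), 5)),
    random = with_local_seed(seed, {
      P <- matrix(runif(n * n, min = 0.01, max = 1), n, n)
      transition_matrix(sweep(P, 2, colSums(P), "/"))
    }),
    model = build_transition_matrix(model_params(N, mu, c)))
}
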