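# Inbreeding coefficient F_IS per state, limiting F_IS distributions,
# and the divergence statistics / G-test used to compare distributions
# derived from original and sparse-approximate matrices.

#' Inbreeding coefficient F_IS of genotype states
#'
#' `F_IS = 1 - nu_aA / (2 nu_a nu_A)` with allele frequencies
#' `nu_a = nu_aa + nu_aA/2`, `nu_A = nu_AA + nu_aA/2`: the relative
#' deficit (positive) or excess (negative) of heterozygotes versus the
#' Hardy-Weinberg expectation.  Undefined (`NA`) for monomorphic states
#' where an allele frequency is zero.
#'
#' @param states Genotype counts `(n_aa, n_aA, n_AA)` — vector, matrix
#'   (one state per row) or a `state_space`.
#' @param N Population size; taken from the `state_space` if given one.
#' @return Numeric vector; `NA` where undefined.
#' @examples
#' fis(c(1, 2, 1), N = 4)  # Hardy-Weinberg: 0
#' fis(c(0, 4, 0), N = 4)  # all heterozygotes: -1
#' @export
fis <- function(states, N = NULL) {
  if (inherits(states, "state_space")) {
    N <- states$N
    states <- states$states
  }
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (is.null(N)) stop("N is required when states is a bare matrix")
  ca <- 2 * states[, 1] + states[, 2]     # allele counts out of 2N
  cA <- 2 * states[, 3] + states[, 2]
  denom <- ca * cA                        # 2 nu_a nu_A = ca*cA / (2N^2)
  out <- ifelse(denom == 0, NA_real_,
                1 - (2 * N * states[, 2]) / denom)
  as.numeric(out)
}

# exact class key: F_IS = 1 - p/q in lowest terms, so equal keys <=>
# exactly equal values (no floating-point binning)
fis_keys <- function(states, N) {
  ca <- 2 * states[, 1] + states[, 2]
  cA <- 2 * states[, 3] + states[, 2]
  p <- 2 * N * states[, 2]
  q <- ca * cA
  g <- mapply(gcd2, p, q)   # gcd(0, q) = q, so p = 0 gives key "0/1"
  ifelse(q == 0, NA_character_, paste0(p / g, "/", q / g))
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Limiting distribution of F_IS
#'
#' Aggregates the probability mass of a limiting distribution by the
#' exact F_IS value of each state (no binning; classes are exact
#' rationals).  Mass on monomorphic states, where F_IS is undefined, is
#' tracked separately as `undefined_mass` and excluded from divergence
#' computations.
#'
#' @param v A `limiting_distribution` (with bound `state_space`) or a
#'   bare probability vector.
#' @param space Required when `v` is a bare vector.
#' @return A `fis_distribution`: list with sorted `values`, `mass` per
#'   class, class `keys` (exact rational labels) and `undefined_mass`.
#' @export
fis_distribution <- function(v, space = NULL) {
  if (inherits(v, "limiting_distribution")) {
    if (is.null(space)) space <- v$space
    v <- v$v
  }
  if (is.null(space)) stop("a state_space is required")
  stopifnot(inherits(space, "state_space"), length(v) == length(space))
  f <- fis(space)
  keys <- fis_keys(space$states, space$N)
  defined <- !is.na(f)
  undefined_mass <- sum(v[!defined])
  agg <- tapply(v[defined], keys[defined], sum)
  vals <- tapply(f[defined], keys[defined], function(x) x[1])
  ord <- order(vals)
  vals <- as.numeric(vals[ord])
  mass <- as.numeric(agg[ord])
  key_sorted <- names(agg)[ord]
  keep <- mass > 0    # only classes the distribution actually occupies
  structure(list(values = vals[keep], mass = mass[keep],
                 keys = key_sorted[keep],
                 undefined_mass = undefined_mass),
            class = "fis_distribution")
}

#' @export
print.fis_distribution <- function(x, ...) {
  cat(sprintf("F_IS distribution: %d classes, undefined mass %.4g\n",
              length(x$values), x$undefined_mass))
  invisible(x)
}

#' Write / read an F_IS distribution as TSV
#'
#' Columns `fis_value`, `mass`; a header comment line records the
#' undefined (monomorphic) mass.
#'
#' @param x A `fis_distribution`.
#' @param path File path.
#' @return `write_fis_distribution`: the path, invisibly;
#'   `read_fis_distribution`: a `fis_distribution`.
#' @export
write_fis_distribution <- function(x, path) {
  stopifnot(inherits(x, "fis_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# undefined_mass\t%.17g", x$undefined_mass), con)
  writeLines(sprintf("# key\t%s", paste(x$keys, collapse = ",")), con)
  writeLines("fis_value\tmass", con)
  writeLines(sprintf("%.17g\t%.17g", x$values, x$mass), con)
  invisible(path)
}

#' @rdname write_fis_distribution
#' @export
read_fis_distribution <- function(path) {
  lines <- readLines(path)
  um <- as.numeric(sub("# undefined_mass\t", "", lines[1], fixed = TRUE))
  keys <- strsplit(sub("# key\t", "", lines[2], fixed = TRUE), ",")[[1]]
  df <- read.table(text = lines[-(1:2)], header = TRUE, sep = "\t")
  structure(list(values = df$fis_value, mass = df$mass, keys = keys,
                 undefined_mass = um),
            class = "fis_distribution")
}

# align two fis_distributions on the union of their classes (by exact
# key when available, else by numeric value); missing classes get mass 0
align_fis <- function(f, g) {
  fk <- if (!is.null(f$keys)) f$keys else as.character(f$values)
  gk <- if (!is.null(g$keys)) g$keys else as.character(g$values)
  allk <- union(fk, gk)
  vals <- rep(NA_real_, length(allk))
  vals[match(fk, allk)] <- f$values
  vals[match(gk, allk)] <- g$values
  fm <- numeric(length(allk)); fm[match(fk, allk)] <- f$mass
  gm <- numeric(length(allk)); gm[match(gk, allk)] <- g$mass
  ord <- order(vals)
  list(values = vals[ord], f = fm[ord], g = gm[ord])
}

#' Divergence between two F_IS distributions
#'
#' Distributions are aligned on the union of their classes (absent
#' classes get mass 0); mass on undefined (monomorphic) states never
#' enters.  Methods: `total_distance` `sum(|f - g|)`; `kl`
#' Kullback-Leibler `sum(f log(f/g))` with `0 log 0 = 0` and infinite
#' terms (g = 0 < f) omitted; `power_divergence`
#' `2/(lambda (lambda+1)) sum(f ((f/g)^lambda - 1))`, infinite terms
#' omitted; `ks` — the Kolmogorov-Smirnov statistic, maximal absolute
#' difference of the cumulative distributions over sorted classes.
#'
#' @param f,g `fis_distribution` objects (total mass including
#'   `undefined_mass` must be 1 within 1e-8).
#' @param method One of `"total_distance"`, `"kl"`,
#'   `"power_divergence"`, `"ks"`.
#' @param lambda Exponent of the power-divergence family (default 2/3,
#'   the conventional recommendation).
#' @return A single non-negative number.
#' @export
fis_divergence <- function(f, g,
                           method = c("total_distance", "kl",
                                      "power_divergence", "ks"),
                           lambda = 2 / 3) {
  method <- match.arg(method)
  for (x in list(f, g)) {
    stopifnot(inherits(x, "fis_distribution"))
    tot <- sum(x$mass) + x$undefined_mass
    if (abs(tot - 1) > 1e-8)
      stop(sprintf("distribution mass sums to %.10g, not 1", tot))
    if (any(x$mass < 0)) stop("negative class mass")
  }
  al <- align_fis(f, g)
  fm <- al$f; gm <- al$g
  switch(method,
    total_distance = sum(abs(fm - gm)),
    kl = {
      keep <- fm > 0 & gm > 0
      sum(fm[keep] * log(fm[keep] / gm[keep]))
    },
    power_divergence = {
      keep <- fm > 0 & gm > 0
      2 / (lambda * (lambda + 1)) *
        sum(fm[keep] * ((fm[keep] / gm[keep])^lambda - 1))
    },
    ks = max(abs(cumsum(fm) - cumsum(gm))))
}

#' G-test comparison of two discrete probability vectors
#'
#' `G = 2 n_eff sum(f log(f / g))` over classes where both masses are
#' positive; classes that would contribute infinite terms
#' (`g = 0 < f`) are omitted and counted.  The p-value uses a
#' chi-square distribution with (retained classes - 1) degrees of
#' freedom.  `n_eff` scales the probabilities to pseudo-counts; the
#' test is intended as a qualitative similarity check.
#'
#' @param f,g Probability vectors of equal length, each summing to 1
#'   within 1e-8 (e.g. aligned F_IS class masses renormalized, or raw
#'   eigenvectors).
#' @param n_eff Pseudo-count scale (default 1000).
#' @return List with `statistic`, `df`, `p_value`, `omitted` (number of
#'   dropped classes).
#' @export
g_test <- function(f, g, n_eff = 1000) {
  if (length(f) != length(g)) stop("vectors must have equal length")
  if (abs(sum(f) - 1) > 1e-8 || abs(sum(g) - 1) > 1e-8)
    stop("inputs must each sum to 1")
  active <- f > 0
  omitted <- sum(active & g == 0)
  keep <- f > 0 & g > 0
  if (sum(keep) < 2) stop("fewer than 2 retained classes; G-test undefined")
  G <- 2 * n_eff * sum(f[keep] * log(f[keep] / g[keep]))
  df <- sum(keep) - 1
  list(statistic = G, df = df,
       p_value = pchisq(G, df = df, lower.tail = FALSE),
       omitted = omitted)
}
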