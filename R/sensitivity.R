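# Morris elementary-effects screening of sparse-approximation quality
# over (N, mu, c, s).  One-step-at-a-time trajectories on parameter
# grids; effects are finite differences in normalized grid coordinates.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default parameter grids for the approximation-quality screening
#'
#' Population size `N` 10..100 step 10, mutation rate `mu` by decades
#' 1e-12..1e-3, clonality rate `c` 0.1..1.0 step 0.1, approximation
#' threshold `s` 0.80..0.98 step 0.02.
#'
#' @return Named list of numeric level vectors.
#' @export
default_gsa_grids <- function() {
  list(N = seq(10, 100, by = 10),
       mu = 10^seq(-12, -3),
       c = seq(0.1, 1.0, by = 0.1),
       s = seq(0.80, 0.98, by = 0.02))
}

#' Morris one-step-at-a-time design
#'
#' Draws `r` random trajectories over the parameter grids.  Each
#' trajectory has `k + 1` points (`k` = number of parameters);
#' consecutive points differ in exactly one parameter by one grid step.
#' Parameters are normalized to \[0, 1\] on their grid index (so a
#' decade grid in `mu` is uniform on the exponent), giving the step
#' `Delta_p = 1 / (levels_p - 1)`.
#'
#' @param grids Named list of numeric level vectors (each of length
#'   >= 2), e.g. [default_gsa_grids()].
#' @param r Number of trajectories; the design has `r * (k + 1)`
#'   evaluation points.
#' @param seed Integer seed; identical seeds give identical designs.
#' @return A `morris_design`: list with `points` (data frame of
#'   parameter values, one evaluation point per row, plus `trajectory`
#'   and `step`), `index` (grid indices), `changed` and `signed_delta`
#'   (per step), `delta` per parameter, and the grids.
#' @export
morris_design <- function(grids, r, seed = 1) {
  stopifnot(is.list(grids), length(grids) >= 1, r >= 1)
  if (any(lengths(grids) < 2))
    stop("every parameter grid needs at least 2 levels")
  k <- length(grids)
  L <- lengths(grids)
  with_local_seed(seed, {
    idx_rows <- list()
    changed <- integer(0)
    sdelta <- numeric(0)
    traj <- integer(0)
    step <- integer(0)
    for (t in seq_len(r)) {
      base <- vapply(L, function(l) sample.int(l, 1), integer(1))
      order_p <- sample.int(k)
      cur <- base
      idx_rows[[length(idx_rows) + 1]] <- cur
      traj <- c(traj, t); step <- c(step, 0L)
      changed <- c(changed, NA_integer_); sdelta <- c(sdelta, NA_real_)
      for (p in order_p) {
        dir <- sample(c(-1L, 1L), 1)
        if (cur[p] + dir < 1 || cur[p] + dir > L[p]) dir <- -dir
        cur[p] <- cur[p] + dir
        idx_rows[[length(idx_rows) + 1]] <- cur
        traj <- c(traj, t); step <- c(step, match(p, order_p))
        changed <- c(changed, p)
        sdelta <- c(sdelta, dir / (L[p] - 1))
      }
    }
    index <- do.call(rbind, idx_rows)
    colnames(index) <- names(grids)
    points <- as.data.frame(mapply(function(g, j) g[j],
                                   grids, asplit(index, 2),
                                   SIMPLIFY = FALSE))
    points$trajectory <- traj
    points$step <- step
    structure(list(points = points, index = index, changed = changed,
                   signed_delta = sdelta,
                   delta = setNames(1 / (L - 1), names(grids)),
                   grids = grids, r = r, seed = seed),
              class = "morris_design")
  })
}

#' @export
print.morris_design <- function(x, ...) {
  cat(sprintf("Morris design: %d parameters, %d trajectories, %d evaluation points (seed %d)\n",
              length(x$grids), x$r, nrow(x$points), x$seed))
  invisible(x)
}

#' Elementary effects from evaluated design points
#'
#' For each trajectory step that changes parameter `p` by signed
#' normalized step `Delta`, the elementary effect is
#' `(y_after - y_before) / Delta`.  Per parameter and output statistic,
#' `mu_star` is the mean absolute effect and `sigma` the standard
#' deviation of the (signed) effects.  Non-finite outputs are omitted
#' from the aggregation (their effects are dropped).
#'
#' @param design A `morris_design`.
#' @param outputs Numeric vector (one output) or matrix/data frame with
#'   one row per evaluation point and one column per output statistic.
#' @return A `morris_result`: list with matrices `mu_star` and `sigma`
#'   (parameters x outputs) and `n_effects` (effects retained).
#' @export
elementary_effects <- function(design, outputs) {
  stopifnot(inherits(design, "morris_design"))
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 1,
                                               dimnames = list(NULL, "y"))
  outputs <- as.matrix(outputs)
  if (nrow(outputs) != nrow(design$points))
    stop("need one output row per design evaluation point")
  k <- length(design$grids)
  pn <- names(design$grids)
  on <- colnames(outputs)
  mu_star <- matrix(NA_real_, k, ncol(outputs), dimnames = list(pn, on))
  sigma <- matrix(NA_real_, k, ncol(outputs), dimnames = list(pn, on))
  n_eff <- matrix(0L, k, ncol(outputs), dimnames = list(pn, on))
  steps <- which(!is.na(design$changed))
  for (o in seq_len(ncol(outputs))) {
    y <- outputs[, o]
    ee <- lapply(seq_len(k), function(p) numeric(0))
    for (i in steps) {
      p <- design$changed[i]
      e <- (y[i] - y[i - 1]) / design$signed_delta[i]
      if (is.finite(e)) ee[[p]] <- c(ee[[p]], e)
    }
    for (p in seq_len(k)) {
      if (length(ee[[p]]) == 0)
        stop(sprintf("no finite elementary effects for parameter '%s' in output '%s'",
                     pn[p], on[o]))
      mu_star[p, o] <- mean(abs(ee[[p]]))
      sigma[p, o] <- if (length(ee[[p]]) > 1) sd(ee[[p]]) else 0
      n_eff[p, o] <- length(ee[[p]])
    }
  }
  structure(list(mu_star = mu_star, sigma = sigma, n_effects = n_eff),
            class = "morris_result")
}

#' @export
print.morris_result <- function(x, ...) {
  cat("Morris elementary effects (mu_star):\n")
  print(round(x$mu_star, 4))
  cat("sigma:\n")
  print(round(x$sigma, 4))
  invisible(x)
}

#' Screening of sparse-approximation quality over the parameter space
#'
#' For every design point `(N, mu, c, s)`: build the dense transition
#' matrix, sparse-approximate it at threshold `s`, compute both limiting
#' F_IS distributions, and record the sparse density together with the
#' divergence statistics between the original and approximate
#' distributions (total distance, Kullback-Leibler, power divergence,
#' Kolmogorov-Smirnov) and the G-test p-value.  Elementary effects are
#' then aggregated per output.  Per-point failures are recorded as `NA`
#' and omitted from the aggregation, not fatal.
#'
#' @param grids Parameter grids (default [default_gsa_grids()]).
#' @param r Trajectories; the printed design size is `r * 5` for the
#'   four model parameters (`r = 30` gives 150 evaluations).
#' @param seed Integer seed.
#' @param n_eff Pseudo-count scale of the G-test.
#' @param progress Emit a message per evaluated point.
#' @return List with the `design`, per-point `outputs` data frame and
#'   the `effects` (`morris_result`).
#' @export
run_gsa <- function(grids = default_gsa_grids(), r = 30, seed = 1,
                    n_eff = 1000, progress = FALSE) {
  design <- morris_design(grids, r, seed)
  pts <- design$points
  out_names <- c("density", "total_distance", "kl", "power_divergence",
                 "ks", "g_test_p")
  outputs <- matrix(NA_real_, nrow(pts), length(out_names),
                    dimnames = list(NULL, out_names))
  cache_key <- ""
  dense <- NULL; v_dense <- NULL; fis_dense <- NULL
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch({
      key <- paste(pts$N[i], pts$mu[i], pts$c[i])
      if (!identical(key, cache_key)) {
        params <- model_params(pts$N[i], pts$mu[i], pts$c[i])
        dense <- build_transition_matrix(params)
        v_dense <- dominant_eigenvector(dense)
        fis_dense <- fis_distribution(v_dense)
        cache_key <- key
      }
      sparse <- approximate_matrix(dense, pts$s[i])
      v_sparse <- dominant_eigenvector(sparse)
      fis_sparse <- fis_distribution(v_sparse)
      al <- align_fis(fis_dense, fis_sparse)
      gt <- tryCatch(g_test(al$f / sum(al$f), al$g / sum(al$g), n_eff),
                     error = function(e) list(p_value = NA_real_))
      c(density = matrix_density(sparse),
        total_distance = fis_divergence(fis_dense, fis_sparse,
                                        "total_distance"),
        kl = fis_divergence(fis_dense, fis_sparse, "kl"),
        power_divergence = fis_divergence(fis_dense, fis_sparse,
                                          "power_divergence"),
        ks = fis_divergence(fis_dense, fis_sparse, "ks"),
        g_test_p = gt$p_value)
    }, error = function(e) {
      warning(sprintf("design point %d (N=%g, mu=%g, c=%g, s=%g) failed: %s",
                      i, pts$N[i], pts$mu[i], pts$c[i], pts$s[i],
                      conditionMessage(e)), call. = FALSE)
      setNames(rep(NA_real_, length(out_names)), out_names)
    })
    outputs[i, ] <- res
    if (progress)
      message(sprintf("[gsa] point %d/%d done", i, nrow(pts)))
  }
  # aggregate per output so one degenerate statistic (e.g. an undefined
  # G-test at an extreme grid corner) cannot sink the others
  k <- length(design$grids)
  mu_star <- sigma <- matrix(NA_real_, k, length(out_names),
                             dimnames = list(names(design$grids), out_names))
  n_eff_m <- matrix(0L, k, length(out_names),
                    dimnames = dimnames(mu_star))
  for (cn in out_names) {
    e <- tryCatch(elementary_effects(design, outputs[, cn, drop = FALSE]),
                  error = function(err) {
                    warning(sprintf("output '%s': %s", cn,
                                    conditionMessage(err)), call. = FALSE)
                    NULL
                  })
    if (!is.null(e)) {
      mu_star[, cn] <- e$mu_star[, 1]
      sigma[, cn] <- e$sigma[, 1]
      n_eff_m[, cn] <- e$n_effects[, 1]
    }
  }
  effects <- structure(list(mu_star = mu_star, sigma = sigma,
                            n_effects = n_eff_m), class = "morris_result")
  list(design = design, outputs = cbind(pts, as.data.frame(outputs)),
       effects = effects)
}
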