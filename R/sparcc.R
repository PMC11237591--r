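#' SparCC compositional correlation estimation
#'
#' Estimates correlations of (log) basis abundances from count compositions,
#' correcting for the spurious correlation that closure induces. For each of
#' `n_iterations` resampled tables (per-sample fractions drawn from a
#' Dirichlet with the counts plus a pseudo-count of 1, the usual treatment of
#' zeros), the variation matrix `t_ij = var(log(x_i / x_j))` is computed,
#' basis variances are solved for under the sparsity assumption, and the
#' strongest correlated pairs (above `exclusion_threshold`) are iteratively
#' excluded from the basis system for up to `exclusion_rounds` rounds. The
#' returned matrix is the entrywise average across iterations, symmetric
#' with unit diagonal and entries clipped to `[-1, 1]`.
#'
#' @param table A [community_table()] or a taxa-by-samples count matrix with
#'   at least 4 taxa.
#' @param n_iterations Number of Dirichlet-resampled estimates averaged.
#' @param exclusion_rounds Maximum strongly-correlated pairs excluded from
#'   the basis-variance system.
#' @param exclusion_threshold Absolute correlation above which a pair can be
#'   excluded.
#' @param seed RNG seed.
#' @return Symmetric correlation matrix with taxon dimnames.
#' @export
sparcc <- function(table, n_iterations = 20, exclusion_rounds = 10,
                   exclusion_threshold = 0.1, seed = 1) {
  counts <- if (inherits(table, "community_table")) table$counts else
    as.matrix(table)
  d <- nrow(counts)
  if (d < 4) abort("SparCC needs at least 4 taxa (basis system unsolvable).")
  with_stream(seed, "sparcc", {
    acc <- matrix(0, d, d)
    for (it in seq_len(n_iterations)) {
      logf <- log(apply(counts, 2, function(x) {
        g <- stats::rgamma(d, shape = x + 1)
        g / sum(g)
      }))
      acc <- acc + basis_correlation(logf, exclusion_rounds,
                                     exclusion_threshold)
    }
    rho <- acc / n_iterations
    rho <- (rho + t(rho)) / 2
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    dimnames(rho) <- list(rownames(counts), rownames(counts))
    rho
  })
}

# One basis-correlation estimate from a d x n matrix of log fractions.
basis_correlation <- function(logf, exclusion_rounds, exclusion_threshold) {
  d <- nrow(logf)
  cv <- stats::cov(t(logf))
  v <- diag(cv)
  tmat <- outer(v, v, "+") - 2 * cv          # variation matrix
  m <- matrix(1, d, d); diag(m) <- d - 1     # sparsity basis system
  tvec <- rowSums(tmat)
  solve_rho <- function() {
    w <- tryCatch(solve(m, tvec), error = function(e) {
      abort("Singular basis-variance system in SparCC.")
    })
    w <- pmax(w, 1e-12)
    rho <- (outer(w, w, "+") - tmat) / (2 * sqrt(outer(w, w)))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- solve_rho()
  excl <- matrix(FALSE, d, d)
  for (r in seq_len(exclusion_rounds)) {
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- 0
    cand[excl] <- 0
    top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[top[1], top[2]] <= exclusion_threshold) break
    i <- top[1]; j <- top[2]
    excl[i, j] <- excl[j, i] <- TRUE
    tvec[i] <- tvec[i] - tmat[i, j]
    tvec[j] <- tvec[j] - tmat[i, j]
    m[i, i] <- m[i, i] - 1; m[j, j] <- m[j, j] - 1
    m[i, j] <- m[j, i] <- 0
    rho <- solve_rho()
  }
  rho
}

#' Bootstrap p-values for SparCC correlations
#'
#' Two-sided p-values against zero from the bootstrap distribution of each
#' correlation: samples (columns) are resampled with replacement
#' `n_bootstrap` times, SparCC is re-run on each resample, and
#' `p = min(1, 2 * (min(#boot <= 0, #boot >= 0) + 1) / (B + 1))`, so p is
#' never exactly zero.
#'
#' @inheritParams sparcc
#' @param n_bootstrap Number of bootstrap resamples (>= 50).
#' @return Symmetric matrix of p-values in `(0, 1]` (diagonal 1).
#' @export
edge_pvalues <- function(table, n_bootstrap = 100, n_iterations = 5,
                         exclusion_rounds = 10, exclusion_threshold = 0.1,
                         seed = 1) {
  counts <- if (inherits(table, "community_table")) table$counts else
    as.matrix(table)
  if (n_bootstrap < 50) abort("Need n_bootstrap >= 50.")
  d <- nrow(counts); n <- ncol(counts)
  n_pos <- matrix(0L, d, d); n_neg <- matrix(0L, d, d)
  for (b in seq_len(n_bootstrap)) {
    idx <- with_stream(seed, paste0("sparcc_boot_idx", b),
                       sample.int(n, n, replace = TRUE))
    rb <- sparcc(counts[, idx, drop = FALSE], n_iterations = n_iterations,
                 exclusion_rounds = exclusion_rounds,
                 exclusion_threshold = exclusion_threshold,
                 seed = substream_seed(seed, paste0("sparcc_boot", b)))
    n_pos <- n_pos + (rb >= 0)
    n_neg <- n_neg + (rb <= 0)
  }
  p <- 2 * (pmin(n_pos, n_neg) + 1) / (n_bootstrap + 1)
  p[p > 1] <- 1
  diag(p) <- 1
  dimnames(p) <- list(rownames(counts), rownames(counts))
  p
}
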