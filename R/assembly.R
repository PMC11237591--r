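#' Between-community mean nearest-taxon distance (beta-MNTD)
#'
#' For every taxon in one community, the phylogenetic distance to its nearest
#' taxon in the other community, averaged (abundance-weighted by default)
#' and symmetrised over the two directions. Identical communities give 0.
#'
#' @param x,y Named count vectors (names must appear in the distance matrix /
#'   tree).
#' @param phy A rooted `ape::phylo` tree or a patristic distance matrix.
#' @param abundance_weighted Weight each taxon by its relative abundance
#'   (default) or equally.
#' @return Non-negative numeric.
#' @export
beta_mntd <- function(x, y, phy, abundance_weighted = TRUE) {
  dmat <- phylo_dist(phy)
  xi <- names(x)[x > 0]; yi <- names(y)[y > 0]
  if (length(xi) == 0 || length(yi) == 0) abort("Empty community.")
  miss <- setdiff(c(xi, yi), rownames(dmat))
  if (length(miss) > 0) {
    abort(paste0("Taxa absent from tree: ", paste(miss, collapse = ", ")))
  }
  bmntd_from_dist(dmat[xi, yi, drop = FALSE],
                  x[xi], y[yi], abundance_weighted)
}

phylo_dist <- function(phy) {
  if (inherits(phy, "phylo")) return(stats::cophenetic(phy))
  m <- as.matrix(phy)
  if (is.null(rownames(m))) abort("Distance matrix needs taxon names.")
  m
}

# dxy: |x-present| x |y-present| patristic distances
bmntd_from_dist <- function(dxy, wx, wy, abundance_weighted) {
  minx <- apply(dxy, 1, min)   # nearest neighbour in y for each taxon of x
  miny <- apply(dxy, 2, min)
  if (abundance_weighted) {
    (sum(minx * wx / sum(wx)) + sum(miny * wy / sum(wy))) / 2
  } else {
    (mean(minx) + mean(miny)) / 2
  }
}

#' Beta nearest-taxon index (betaNTI)
#'
#' Standardised effect size of the observed [beta_mntd()] against a null in
#' which taxon labels are shuffled across the tips of the taxon pool:
#' `(obs - mean(null)) / sd(null)`. `|betaNTI| > 2` indicates that the pair's
#' phylogenetic turnover deviates from chance (selection).
#'
#' @inheritParams beta_mntd
#' @param n_null Number of label shuffles (>= 99).
#' @param pool Taxon ids defining the shuffle pool (default: all taxa in the
#'   distance matrix).
#' @param seed RNG seed.
#' @return A single numeric betaNTI value.
#' @export
bnti <- function(x, y, phy, n_null = 999, abundance_weighted = TRUE,
                 pool = NULL, seed = 1) {
  assert_count(n_null, "n_null", min = 99)
  dmat <- phylo_dist(phy)
  pool <- pool %||% rownames(dmat)
  dmat <- dmat[pool, pool, drop = FALSE]
  xi <- match(names(x)[x > 0], pool); yi <- match(names(y)[y > 0], pool)
  if (anyNA(xi) || anyNA(yi)) abort("Community taxa missing from pool.")
  wx <- x[x > 0]; wy <- y[y > 0]
  obs <- bmntd_from_dist(dmat[xi, yi, drop = FALSE], wx, wy,
                         abundance_weighted)
  nulls <- with_stream(seed, "bnti", {
    vapply(seq_len(n_null), function(b) {
      idx <- sample.int(length(pool))
      bmntd_from_dist(dmat[idx[xi], idx[yi], drop = FALSE], wx, wy,
                      abundance_weighted)
    }, numeric(1))
  })
  s <- stats::sd(nulls)
  if (s == 0) {
    abort("Null beta-MNTD has zero variance (degenerate tree or pool).")
  }
  (obs - mean(nulls)) / s
}

#' Modified Raup-Crick index on Bray-Curtis (RC)
#'
#' Compares the observed Bray-Curtis dissimilarity of a sample pair against
#' null communities assembled by probabilistic draws that preserve each
#' community's richness and total abundance, with species recruited
#' proportionally to their occupancy in the species pool and individuals
#' assigned proportionally to mean relative abundance.
#' `RC = 2 * P(null < obs, ties counted half) - 1`, in `[-1, 1]`.
#'
#' @param x,y Named count vectors.
#' @param n_null Number of null assemblies (>= 99).
#' @param occupancy,rel_abund Optional named pool statistics (number of
#'   communities occupied; mean relative abundance). Defaults are derived
#'   from the pair itself, but supplying group-level pools is recommended.
#' @param seed RNG seed.
#' @return RC value in `[-1, 1]`.
#' @export
rc_bray <- function(x, y, n_null = 999, occupancy = NULL, rel_abund = NULL,
                    seed = 1) {
  assert_count(n_null, "n_null", min = 99)
  if (sum(x) == 0 || sum(y) == 0) abort("Empty community.")
  if (is.null(occupancy) || is.null(rel_abund)) {
    taxa <- union(names(x)[x > 0], names(y)[y > 0])
    xm <- stats::setNames(numeric(length(taxa)), taxa)
    ym <- xm
    xm[names(x)[x > 0]] <- x[x > 0]; ym[names(y)[y > 0]] <- y[y > 0]
    occupancy <- occupancy %||% ((xm > 0) + (ym > 0))
    rel_abund <- rel_abund %||% ((xm / sum(xm) + ym / sum(ym)) / 2)
  }
  pool <- names(occupancy)
  obs <- bray_curtis_pair_on(x, y, pool)
  rx <- sum(x > 0); ry <- sum(y > 0)
  nx <- sum(x); ny <- sum(y)
  nulls <- with_stream(seed, "rc_bray", {
    vapply(seq_len(n_null), function(b) {
      a <- null_assemble(pool, rx, nx, occupancy, rel_abund)
      bb <- null_assemble(pool, ry, ny, occupancy, rel_abund)
      bray_curtis(a, bb)
    }, numeric(1))
  })
  (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null * 2 - 1
}

bray_curtis_pair_on <- function(x, y, pool) {
  xv <- stats::setNames(numeric(length(pool)), pool)
  yv <- xv
  xv[intersect(names(x), pool)] <- x[intersect(names(x), pool)]
  yv[intersect(names(y), pool)] <- y[intersect(names(y), pool)]
  bray_curtis(xv, yv)
}

# One null community: `richness` species by occupancy-weighted sampling
# without replacement, one individual each, remaining individuals
# multinomially by relative abundance.
null_assemble <- function(pool, richness, n_ind, occupancy, rel_abund) {
  richness <- min(richness, length(pool))
  picked <- sample(seq_along(pool), richness, prob = occupancy)
  counts <- stats::setNames(numeric(length(pool)), pool)
  counts[picked] <- 1
  extra <- n_ind - richness
  if (extra > 0) {
    p <- rel_abund[picked]
    if (sum(p) <= 0) p <- rep(1, richness)
    counts[picked] <- counts[picked] +
      stats::rmultinom(1L, extra, p)[, 1L]
  }
  counts
}

#' Assign an assembly process from (betaNTI, RC)
#'
#' The two-stage decision rule: `betaNTI < -2` homogeneous selection,
#' `betaNTI > 2` heterogeneous selection; otherwise `RC < -0.95` homogenizing
#' dispersal, `RC > 0.95` dispersal limitation, and the remainder drift.
#' Inequalities are strict, so values exactly on a boundary fall through to
#' the next rule.
#'
#' @param bnti,rc Numeric vectors (recycled to common length).
#' @return Character vector of process names.
#' @export
classify_process <- function(bnti, rc) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n); rc <- rep_len(rc, n)
  if (any(!is.finite(bnti)) || any(!is.finite(rc))) {
    abort("betaNTI and RC must be finite.")
  }
  ifelse(bnti < -2, "homogeneous_selection",
         ifelse(bnti > 2, "heterogeneous_selection",
                ifelse(rc < -0.95, "homogenizing_dispersal",
                       ifelse(rc > 0.95, "dispersal_limitation", "drift"))))
}

assembly_processes <- c("homogeneous_selection", "heterogeneous_selection",
                        "homogenizing_dispersal", "dispersal_limitation",
                        "drift")

#' Per-pair assembly statistics for a community table
#'
#' Computes betaNTI and RC for every within-group sample pair and classifies
#' the assembly process of each pair. The taxon pool for the null models is
#' the set of taxa present in the group.
#'
#' @param table A [community_table()].
#' @param phy Tree or patristic distance matrix covering the table's taxa.
#' @param group_by Metadata column defining sample groups (default
#'   `"habitat"`); use a constant column to pool all samples.
#' @param n_null Null draws for both betaNTI and RC.
#' @param seed RNG seed.
#' @return Tibble: `sample_a`, `sample_b`, `group`, `bnti`, `rc`, `process`.
#' @export
assembly_pairs <- function(table, phy, group_by = "habitat", n_null = 999,
                           seed = 1) {
  stopifnot(inherits(table, "community_table"))
  md <- table$metadata
  if (!group_by %in% names(md)) abort(paste0("No metadata column ", group_by))
  dmat <- phylo_dist(phy)
  groups <- split(md$sample, md[[group_by]])
  out <- purrr::imap(groups, function(samps, g) {
    if (length(samps) < 2) return(NULL)
    sub <- table$counts[, samps, drop = FALSE]
    pool <- rownames(sub)[rowSums(sub) > 0]
    occ <- rowSums(sub[pool, , drop = FALSE] > 0)
    rel <- rowMeans(sweep(sub[pool, , drop = FALSE], 2, colSums(sub), "/"))
    pairs <- utils::combn(samps, 2)
    purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      xs <- sub[pool, a]; ys <- sub[pool, b]
      pair_seed <- substream_seed(seed, paste("pair", g, a, b))
      bn <- bnti(xs[xs > 0], ys[ys > 0], dmat[pool, pool, drop = FALSE],
                 n_null = n_null, pool = pool, seed = pair_seed)
      rc <- rc_bray(xs[xs > 0], ys[ys > 0], n_null = n_null,
                    occupancy = occ, rel_abund = rel, seed = pair_seed)
      tibble(sample_a = a, sample_b = b, group = g, bnti = bn, rc = rc)
    }) |> bind_rows()
  }) |> bind_rows()
  out$process <- classify_process(out$bnti, out$rc)
  out
}

#' Summarise assembly processes per group
#'
#' Exact per-process fractions plus the deterministic (selection) and
#' stochastic (dispersal + drift) totals. The five fractions sum to 1
#' exactly for every group.
#'
#' @param pairs Tibble from [assembly_pairs()] (needs `group`, `process`).
#' @return Tibble with one row per group x process: `n_pairs`, `fraction`,
#'   and the group totals `deterministic` and `stochastic`.
#' @export
summarize_assembly <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("group", "process") %in% names(pairs)))
  bad <- setdiff(unique(pairs$process), assembly_processes)
  if (length(bad) > 0) {
    abort(paste0("Unknown processes: ", paste(bad, collapse = ", ")))
  }
  purrr::imap(split(pairs, pairs$group), function(df, g) {
    n <- nrow(df)
    cnt <- vapply(assembly_processes, function(p) sum(df$process == p),
                  integer(1))
    frac <- cnt / n
    # force the fractions to sum to 1 exactly (counts are exact; division
    # can round): push any residual into the largest fraction
    for (k in 1:2) {
      res <- 1 - sum(frac)
      if (res == 0) break
      i <- which.max(frac)
      frac[i] <- frac[i] + res
    }
    det <- sum(frac[1:2])
    tibble(group = g, process = assembly_processes,
           n_pairs = cnt, fraction = unname(frac),
           deterministic = det, stochastic = 1 - det)
  }) |> bind_rows()
}

#' Keep a subset of taxa in a community table
#'
#' @param table A [community_table()].
#' @param taxa Taxon ids to keep.
#' @param drop_empty_samples Drop samples left with zero reads.
#' @return A [community_table()].
#' @export
keep_taxa <- function(table, taxa, drop_empty_samples = TRUE) {
  stopifnot(inherits(table, "community_table"))
  taxa <- intersect(taxa, rownames(table$counts))
  if (length(taxa) == 0) abort("No requested taxa present in the table.")
  m <- table$counts[taxa, , drop = FALSE]
  keep <- if (drop_empty_samples) colSums(m) > 0 else rep(TRUE, ncol(m))
  community_table(m[, keep, drop = FALSE], table$metadata[keep, ])
}
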