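#' Niche-breadth indices
#'
#' Three per-taxon indices over the habitat dimension: Levins' niche breadth
#' `B = 1 / sum(p_i^2)` (inverse Simpson concentration of habitat-use
#' proportions; 1 = single habitat, n = uniform use of n habitats), Shannon
#' niche breadth `H = -sum(p_i * log(p_i))` in nats, and occurrence frequency
#' (the fraction of samples in which the taxon is present).
#'
#' @param habitat_shares Numeric vector of habitat-use proportions summing
#'   to 1 (see [habitat_shares()]).
#' @return A single numeric value.
#' @export
#' @examples
#' levins_breadth(rep(0.2, 5))   # 5: uniform use of 5 habitats
#' shannon_breadth(c(1, 0, 0))   # 0: single habitat
levins_breadth <- function(habitat_shares) {
  p <- check_shares(habitat_shares)
  1 / sum(p^2)
}

#' @rdname levins_breadth
#' @export
shannon_breadth <- function(habitat_shares) {
  p <- check_shares(habitat_shares)
  p <- p[p > 0]
  -sum(p * log(p))
}

check_shares <- function(p) {
  if (!is.numeric(p) || any(p < 0)) abort("Shares must be non-negative.")
  s <- sum(p)
  if (s <= 0) abort("Taxon absent everywhere: shares sum to 0.")
  if (abs(s - 1) > 1e-6) abort("Shares must sum to 1.")
  p / s
}

#' @rdname levins_breadth
#' @param counts Numeric vector of a taxon's counts across samples.
#' @export
occurrence_frequency <- function(counts) {
  if (length(counts) == 0) abort("Need at least one sample.")
  mean(counts > 0)
}

#' Habitat-use proportions of every taxon
#'
#' A taxon's habitat share is its mean relative abundance within each
#' habitat (averaging within habitat first balances unequal sample counts
#' per habitat), normalised across habitats to a simplex.
#'
#' @param table A [community_table()].
#' @return Matrix (taxa x habitats) of shares; rows sum to 1.
#' @export
habitat_shares <- function(table) {
  stopifnot(inherits(table, "community_table"))
  shares_matrix(table$counts, table$metadata$habitat)
}

# counts: taxa x samples; habitat: per-sample labels
shares_matrix <- function(counts, habitat) {
  tot <- colSums(counts)
  if (any(tot == 0)) abort("Zero-total sample in table.")
  rel <- sweep(counts, 2, tot, "/")
  hab <- factor(habitat)
  agg <- vapply(levels(hab), function(h) {
    rowMeans(rel[, hab == h, drop = FALSE])
  }, numeric(nrow(counts)))
  rs <- rowSums(agg)
  if (any(rs == 0)) {
    abort(paste0("Taxa absent from every sample: ",
                 paste(rownames(counts)[rs == 0], collapse = ", ")))
  }
  agg / rs
}

# The three indices for one (possibly permuted) count matrix; returns a
# taxa x 3 matrix (levins, shannon, occupancy). Hot path of the classifier,
# so everything is matrix algebra.
niche_index_matrix <- function(counts, habitat) {
  p <- shares_matrix(counts, habitat)
  lv <- 1 / rowSums(p^2)
  lp <- ifelse(p > 0, log(p), 0)
  sh <- -rowSums(p * lp)
  cbind(levins = lv, shannon = sh, occupancy = rowMeans(counts > 0))
}

#' Classify taxa as habitat generalists, specialists or opportunists
#'
#' Compares each taxon's three niche-breadth indices ([levins_breadth()],
#' [shannon_breadth()], [occurrence_frequency()]) against a permutation null
#' of the community table. A taxon is called a generalist when its observed
#' value exceeds the upper envelope bound for all three indices, a specialist
#' when below the lower bound for all three, and an opportunist otherwise.
#'
#' Null schemes (`null_method`):
#' \describe{
#'   \item{`"shuffle"` (default)}{Within-sample permutation of the abundance
#'     table: taxon identities are shuffled independently within each sample,
#'     holding every sample's total and abundance distribution fixed. Under
#'     this null a taxon's profile across samples is an exchangeable draw
#'     from the per-sample abundance pools, so taxa that are consistently
#'     even across habitats rise above the envelope and taxa concentrated in
#'     one habitat fall below it.}
#'   \item{`"multinomial"`}{Each taxon's total reads are re-assigned to
#'     samples by a multinomial draw with probabilities proportional to
#'     sample totals. Preserves taxon totals and expected depths; note that
#'     on a rarefied table this null is the maximal-evenness placement, so it
#'     can detect specialists but (by construction) almost never generalists.}
#'   \item{`"quasiswap"`}{Count quasiswap via [vegan::permatswap()],
#'     preserving row sums, column sums and table fill.}
#' }
#'
#' @param table A rarefied [community_table()] (equal sample depths
#'   recommended).
#' @param n_perm Number of permutations (>= 100).
#' @param envelope Central null mass defining the envelope (default 0.95,
#'   i.e. empirical 2.5%/97.5% quantiles).
#' @param null_method Null scheme, see Details.
#' @param seed RNG seed.
#' @return A tibble of niche profiles, one row per taxon: the three observed
#'   indices, their per-taxon null envelope bounds, `total_reads`, `class`,
#'   and placeholder strict flags (filled by [strict_filter()]). Attributes
#'   record `n_perm`, `null_method`, `envelope` and `seed`.
#' @export
null_classify <- function(table, n_perm = 1000, envelope = 0.95,
                          null_method = c("shuffle", "multinomial",
                                          "quasiswap"),
                          seed = 1) {
  stopifnot(inherits(table, "community_table"))
  null_method <- match.arg(null_method)
  assert_count(n_perm, "n_perm", min = 100)
  assert_prob(envelope, "envelope")
  counts <- table$counts
  habitat <- table$metadata$habitat
  obs <- niche_index_matrix(counts, habitat)
  n_taxa <- nrow(counts)

  nulls <- with_stream(seed, paste0("niche_null_", null_method), {
    out <- array(NA_real_, c(n_taxa, n_perm, 3L))
    if (null_method == "quasiswap") {
      done <- 0L
      while (done < n_perm) {
        k <- min(50L, n_perm - done)
        pm <- vegan::permatswap(t(counts), method = "quasiswap", times = k)
        for (i in seq_len(k)) {
          out[, done + i, ] <- niche_index_matrix(t(pm$perm[[i]]), habitat)
        }
        done <- done + k
      }
    } else {
      totals <- colSums(counts)
      row_tot <- rowSums(counts)
      for (b in seq_len(n_perm)) {
        perm <- if (null_method == "shuffle") {
          apply(counts, 2, function(x) x[sample.int(length(x))])
        } else {
          t(vapply(row_tot, function(r) {
            stats::rmultinom(1L, r, totals)[, 1L]
          }, numeric(ncol(counts))))
        }
        out[, b, ] <- niche_index_matrix(perm, habitat)
      }
    }
    out
  })

  a <- (1 - envelope) / 2
  qs <- function(j, p) apply(nulls[, , j], 1, stats::quantile, probs = p,
                             names = FALSE)
  lo <- vapply(1:3, qs, numeric(n_taxa), p = a)
  hi <- vapply(1:3, qs, numeric(n_taxa), p = 1 - a)

  is_gen <- rowSums(obs > hi) == 3L
  is_spc <- rowSums(obs < lo) == 3L
  profiles <- tibble(
    taxon = rownames(counts),
    total_reads = as.integer(rowSums(counts)),
    levins_b = obs[, 1], shannon_h = obs[, 2], occ_f = obs[, 3],
    levins_lo = lo[, 1], levins_hi = hi[, 1],
    shannon_lo = lo[, 2], shannon_hi = hi[, 2],
    occ_lo = lo[, 3], occ_hi = hi[, 3],
    class = ifelse(is_gen, "generalist",
                   ifelse(is_spc, "specialist", "opportunist")),
    strict_generalist = FALSE, strict_specialist = FALSE
  )
  structure(profiles, n_perm = n_perm, null_method = null_method,
            envelope = envelope, seed = seed,
            class = c("niche_profiles", class(profiles)))
}

#' Strict generalists and specialists
#'
#' Applies the two strictness rules used for downstream analyses: strict
#' generalists are the classified generalists at or above the
#' `percentile`-th percentile (default 90th, computed among generalists) of
#' all three index values jointly; strict specialists are classified
#' specialists with more than `min_reads` total reads (default 50), guarding
#' against rare taxa that are merely below detection in most habitats. All
#' other taxa are opportunists for downstream stages (`class_strict`).
#'
#' @param profiles Output of [null_classify()].
#' @param percentile Strict-generalist percentile cutoff (inclusive).
#' @param min_reads Strict-specialist minimum total reads (exclusive).
#' @return The profiles tibble with `strict_generalist`,
#'   `strict_specialist` and `class_strict` filled in.
#' @export
strict_filter <- function(profiles, percentile = 0.9, min_reads = 50) {
  stopifnot(is.data.frame(profiles))
  gen <- profiles$class == "generalist"
  strict_gen <- rep(FALSE, nrow(profiles))
  if (any(gen)) {
    qb <- stats::quantile(profiles$levins_b[gen], percentile, names = FALSE)
    qh <- stats::quantile(profiles$shannon_h[gen], percentile, names = FALSE)
    qf <- stats::quantile(profiles$occ_f[gen], percentile, names = FALSE)
    strict_gen <- gen & profiles$levins_b >= qb & profiles$shannon_h >= qh &
      profiles$occ_f >= qf
  }
  strict_spc <- profiles$class == "specialist" & profiles$total_reads > min_reads
  profiles$strict_generalist <- strict_gen
  profiles$strict_specialist <- strict_spc
  profiles$class_strict <- ifelse(strict_gen, "generalist",
                                  ifelse(strict_spc, "specialist",
                                         "opportunist"))
  profiles
}
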