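#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x - y|) / sum(x + y)` over a shared taxon set; 0 for identical
#' communities, 1 for disjoint ones.
#'
#' @param x,y Non-negative count (or abundance) vectors over the same taxa.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must cover the same taxa.")
  s <- sum(x) + sum(y)
  if (s == 0) abort("Both communities are empty.")
  sum(abs(x - y)) / s
}

#' Normalised weighted UniFrac dissimilarity
#'
#' Branch-length-weighted difference between the relative-abundance flows of
#' two communities on a shared rooted tree, normalised so identical
#' communities give 0 and communities on disjoint subtrees give 1:
#' `sum(l_e |A_e - B_e|) / sum(l_e (A_e + B_e))`, where `A_e`, `B_e` are the
#' fractions of each community descending from branch `e`.
#'
#' @param x,y Named count vectors (names = tree tips) or unnamed vectors
#'   aligned to `tree$tip.label`.
#' @param tree A rooted `ape::phylo` tree covering all taxa with non-zero
#'   counts.
#' @return Dissimilarity in `[0, 1]`.
#' @export
weighted_unifrac <- function(x, y, tree) {
  stopifnot(inherits(tree, "phylo"))
  align <- function(v) {
    if (!is.null(names(v))) {
      miss <- setdiff(names(v)[v > 0], tree$tip.label)
      if (length(miss) > 0) {
        abort(paste0("Taxa missing from tree: ", paste(miss, collapse = ", ")))
      }
      out <- stats::setNames(numeric(ape::Ntip(tree)), tree$tip.label)
      out[intersect(names(v), tree$tip.label)] <-
        v[intersect(names(v), tree$tip.label)]
      out
    } else {
      if (length(v) != ape::Ntip(tree)) {
        abort("Unnamed vectors must match the number of tips.")
      }
      stats::setNames(v, tree$tip.label)
    }
  }
  xa <- align(x); ya <- align(y)
  if (sum(xa) == 0 || sum(ya) == 0) abort("Empty community.")
  px <- xa / sum(xa); py <- ya / sum(ya)
  n_tip <- ape::Ntip(tree)
  # per-edge descending mass, accumulated tips-to-root in postorder
  re <- ape::reorder.phylo(tree, "postorder")
  mass_x <- mass_y <- numeric(n_tip + tree$Nnode)
  mass_x[seq_len(n_tip)] <- px  # tip numbering is preserved by reorder
  mass_y[seq_len(n_tip)] <- py
  num <- den <- 0
  for (k in seq_len(nrow(re$edge))) {
    par <- re$edge[k, 1]; ch <- re$edge[k, 2]
    a <- mass_x[ch]; b <- mass_y[ch]
    num <- num + re$edge.length[k] * abs(a - b)
    den <- den + re$edge.length[k] * (a + b)
    mass_x[par] <- mass_x[par] + a
    mass_y[par] <- mass_y[par] + b
  }
  if (den == 0) return(0)
  num / den
}

#' Pairwise dissimilarity matrix of a community table
#'
#' @param table A [community_table()].
#' @param method `"bray"` (Bray-Curtis, via [vegan::vegdist()]) or
#'   `"wunifrac"` (normalised weighted UniFrac).
#' @param tree Required for `"wunifrac"`.
#' @return A `dist` object over samples.
#' @export
dissimilarity_matrix <- function(table, method = c("bray", "wunifrac"),
                                 tree = NULL) {
  stopifnot(inherits(table, "community_table"))
  method <- match.arg(method)
  if (method == "bray") {
    return(vegan::vegdist(t(table$counts), method = "bray"))
  }
  if (is.null(tree)) abort("`tree` is required for weighted UniFrac.")
  n <- ncol(table$counts)
  m <- matrix(0, n, n, dimnames = list(colnames(table$counts),
                                       colnames(table$counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- weighted_unifrac(table$counts[, i],
                                             table$counts[, j], tree)
    }
  }
  stats::as.dist(m)
}

#' Distance-decay regression
#'
#' Ordinary least squares of `log(dissimilarity)` on `log(D + 1)` (one is
#' added to the geographic distance D before the logarithm so that
#' zero-distance pairs remain defined). The slope is the spatial turnover
#' rate of the group. Pairs with zero dissimilarity cannot enter the log
#' regression; they are dropped and counted.
#'
#' @param dissimilarities,distances Numeric vectors over sample pairs.
#' @param group Optional label stored with the fit.
#' @return An object of class `distance_decay` wrapping the `lm` fit, with
#'   [generics::tidy()] / [generics::glance()] methods.
#' @export
distance_decay_fit <- function(dissimilarities, distances, group = NA_character_) {
  if (length(dissimilarities) != length(distances)) {
    abort("Dissimilarities and distances must pair up.")
  }
  keep <- dissimilarities > 0
  n_zero <- sum(!keep)
  ds <- dissimilarities[keep]; dd <- distances[keep]
  if (length(ds) < 3) abort("Need at least 3 non-zero pairs for a fit.")
  if (stats::var(dd) == 0) abort("All distances equal: degenerate regressor.")
  fit <- stats::lm(log(ds) ~ log(dd + 1))
  structure(list(lm = fit,
                 beta_slope = unname(stats::coef(fit)[2]),
                 intercept_c = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n_pairs = length(ds), n_zero_dropped = n_zero,
                 group = group),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf(
    "<distance_decay%s> slope %.4f, intercept %.4f, R^2 %.3f, %d pairs%s\n",
    if (is.na(x$group)) "" else paste0(": ", x$group),
    x$beta_slope, x$intercept_c, x$r_squared, x$n_pairs,
    if (x$n_zero_dropped > 0) {
      sprintf(" (%d zero-dissimilarity pairs dropped)", x$n_zero_dropped)
    } else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy distance_decay
#' @export
tidy.distance_decay <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm))$coefficients
  tibble(term = c("intercept_c", "beta_slope"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4],
         group = x$group)
}

#' @method glance distance_decay
#' @export
glance.distance_decay <- function(x, ...) {
  tibble(beta_slope = x$beta_slope, intercept_c = x$intercept_c,
         r.squared = x$r_squared, n_pairs = x$n_pairs,
         n_zero_dropped = x$n_zero_dropped, group = x$group)
}

#' Distance-decay fits per group from a community table
#'
#' Convenience wrapper: computes pairwise dissimilarities and geographic
#' distances between samples and fits [distance_decay_fit()] for each taxon
#' group (e.g. the generalist and specialist subsets of the table).
#'
#' @param table A [community_table()] with `x`, `y` sample coordinates.
#' @param groups Named list of taxon-id vectors, one entry per group.
#' @param method Dissimilarity method passed to [dissimilarity_matrix()].
#' @param tree Tree for `"wunifrac"`.
#' @return Tibble with one row per group ([glance][generics::glance] of each
#'   fit).
#' @export
distance_decay_by_group <- function(table, groups, method = "bray",
                                    tree = NULL) {
  stopifnot(inherits(table, "community_table"))
  md <- table$metadata
  if (!all(c("x", "y") %in% names(md))) abort("Metadata needs x/y coordinates.")
  geo <- as.matrix(stats::dist(cbind(md$x, md$y)))
  purrr::imap(groups, function(taxa, g) {
    sub <- table$counts[intersect(taxa, rownames(table$counts)), ,
                        drop = FALSE]
    ok <- colSums(sub) > 0
    subtab <- community_table(sub[, ok, drop = FALSE], md[ok, ])
    dm <- as.matrix(dissimilarity_matrix(subtab, method, tree))
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    fit <- distance_decay_fit(dm[idx], geo[ok, ok][idx], group = g)
    glance(fit)
  }) |> bind_rows()
}
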