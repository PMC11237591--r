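#' Drop low-count taxa
#'
#' Removes taxa whose total read count across all samples is below
#' `min_total` (default 10, the usual guard against sequencing errors in
#' denoised amplicon tables). Samples are unchanged.
#'
#' @param table A [community_table()].
#' @param min_total Minimum total reads for a taxon to be retained.
#' @return A filtered [community_table()].
#' @export
filter_min_reads <- function(table, min_total = 10) {
  stopifnot(inherits(table, "community_table"))
  keep <- rowSums(table$counts) >= min_total
  if (!any(keep)) {
    abort(sprintf(
      "No taxon reaches %d reads (max total is %d); nothing left to analyse.",
      min_total, max(rowSums(table$counts))))
  }
  community_table(table$counts[keep, , drop = FALSE], table$metadata)
}

#' Rarefy every sample to a common depth
#'
#' Subsamples each sample's reads without replacement (a random permutation
#' of read labels) so that every column sums exactly to `depth`.
#'
#' @param table A [community_table()].
#' @param depth Target reads per sample; defaults to the minimum sample
#'   total. Every sample must have at least `depth` reads.
#' @param seed RNG seed.
#' @return A rarefied [community_table()].
#' @export
rarefy <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "community_table"))
  totals <- colSums(table$counts)
  depth <- depth %||% min(totals)
  low <- totals < depth
  if (any(low)) {
    abort(paste0("Samples below the rarefaction depth (", depth, "): ",
                 paste(colnames(table$counts)[low], collapse = ", ")))
  }
  with_stream(seed, "rarefy", {
    out <- apply(table$counts, 2, function(x) {
      if (sum(x) == depth) return(as.integer(x))
      reads <- rep.int(seq_along(x), x)
      tabulate(reads[sample.int(length(reads), depth)], nbins = length(x))
    })
    dimnames(out) <- dimnames(table$counts)
    community_table(out, table$metadata)
  })
}

#' Good's coverage per sample
#'
#' Sampling completeness `1 - singletons / reads`, where singletons are the
#' taxa observed exactly once in the sample.
#'
#' @param table A [community_table()].
#' @return Tibble with columns `sample`, `habitat`, `reads`, `singletons`,
#'   `coverage`.
#' @export
goods_coverage <- function(table) {
  stopifnot(inherits(table, "community_table"))
  reads <- colSums(table$counts)
  if (any(reads == 0)) {
    abort(paste0("Zero-total samples: ",
                 paste(colnames(table$counts)[reads == 0], collapse = ", ")))
  }
  singles <- colSums(table$counts == 1L)
  tibble(sample = colnames(table$counts),
         habitat = table$metadata$habitat,
         reads = as.integer(unname(reads)),
         singletons = as.integer(unname(singles)),
         coverage = unname(1 - singles / reads))
}
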