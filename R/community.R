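#' Community count table with sample metadata
#'
#' The universal input of the pipeline: an integer taxon-by-sample count
#' matrix together with per-sample metadata (habitat, park, grid
#' coordinates). Constructed from a matrix or read from TSV/BIOM files.
#'
#' @param counts Non-negative integer matrix, taxa in rows and samples in
#'   columns, with unique dimnames.
#' @param metadata Data frame with one row per sample and columns
#'   `sample`, `habitat`, `park`, `x`, `y` (coordinates optional).
#'
#' @return An object of class `community_table`: a list with elements
#'   `counts` (integer matrix) and `metadata` (tibble), aligned by sample.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 7L), 2, 2,
#'             dimnames = list(c("zotu1", "zotu2"), c("s1", "s2")))
#' md <- data.frame(sample = c("s1", "s2"), habitat = c("soil", "water"),
#'                  park = c("p1", "p1"))
#' community_table(m, md)
community_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be a non-negative integer matrix.")
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs taxon rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate taxon ids.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample ids.")
  metadata <- as_tibble(metadata)
  if (!all(c("sample", "habitat") %in% names(metadata))) {
    abort("`metadata` must have columns `sample` and `habitat`.")
  }
  missing <- setdiff(colnames(counts), metadata$sample)
  if (length(missing) > 0) {
    abort(paste0("Samples without metadata: ", paste(missing, collapse = ", ")))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample), ]
  structure(list(counts = counts, metadata = metadata),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d taxa x %d samples, %d habitats\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$habitat))))
  cat(sprintf("  total reads %s, occupancy %.1f%%\n",
              format(sum(x$counts), big.mark = ","),
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' @describeIn community_table Long tibble (taxon, sample, count, metadata).
#' @param x A `community_table`.
#' @param ... Unused.
#' @method as_tibble community_table
#' @export
as_tibble.community_table <- function(x, ...) {
  tibble(
    taxon = rep(rownames(x$counts), ncol(x$counts)),
    sample = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  ) |>
    left_join(x$metadata, by = "sample")
}

habitats_of <- function(table) sort(unique(table$metadata$habitat))

#' Read / write a community table as TSV
#'
#' The count table is stored as taxa rows by sample columns with the first
#' column holding the taxon (zOTU) id; metadata as a sample-per-row TSV.
#'
#' @param counts_file,metadata_file Paths of the two TSV files.
#' @return `read_community_tsv()` returns a [community_table()];
#'   `write_community_tsv()` returns the input invisibly.
#' @export
read_community_tsv <- function(counts_file, metadata_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  md <- utils::read.delim(metadata_file, check.names = FALSE)
  community_table(counts, md)
}

#' @rdname read_community_tsv
#' @param table A `community_table`.
#' @export
write_community_tsv <- function(table, counts_file, metadata_file = NULL) {
  df <- data.frame(zotu = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_file)) {
    utils::write.table(as.data.frame(table$metadata), metadata_file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(table)
}

#' Read / write a community table as BIOM
#'
#' Optional BIOM (JSON, format 1.0) support via the biomformat package;
#' sample metadata travels separately as TSV.
#'
#' @param biom_file Path of the BIOM file.
#' @param metadata Data frame of sample metadata (see [community_table()]),
#'   or path of a metadata TSV.
#' @return `read_community_biom()` returns a [community_table()].
#' @export
read_community_biom <- function(biom_file, metadata) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM support needs the biomformat package.")
  }
  b <- biomformat::read_biom(biom_file)
  counts <- as.matrix(biomformat::biom_data(b))
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, check.names = FALSE)
  }
  community_table(counts, metadata)
}

#' @rdname read_community_biom
#' @param table A `community_table`.
#' @export
write_community_biom <- function(table, biom_file) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM support needs the biomformat package.")
  }
  b <- biomformat::make_biom(table$counts)
  biomformat::write_biom(b, biom_file)
  invisible(table)
}
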