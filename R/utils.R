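#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows count n rename relocate pull across
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom Rcpp sourceCpp
#' @useDynLib habgen, .registration = TRUE
NULL

# Deterministic substream seed: one master seed, one named stream per
# generator / stage, so stages can be re-run independently and still
# reproduce the full-pipeline results. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h) %% 2147480009 + 1)
}

# Evaluate `expr` under a seeded, restored RNG state.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(substream_seed(seed, stream), expr)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, format(min)))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(as.numeric(x))
}
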