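#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive a 28-bit integer sub-seed from a master seed and an arbitrary key.
# Keyed substreams make every stage (root draw, branch evolution, pileups,
# resampling) independently reproducible without a global RNG walk.
substream_seed <- function(seed, ...) {
  h <- rlang::hash(list(as.integer(seed), ...))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

with_substream <- function(seed, ..., expr) {
  withr::with_seed(substream_seed(seed, ...), expr)
}

check_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what), class = "asexdiv_input")
  }
  invisible(x)
}

# Split a nucleotide string into a character vector of single bases.
split_bases <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1L]]

# Split an in-frame coding string into codons.
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("coding sequence length must be divisible by 3", class = "asexdiv_frame")
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

is_acgt <- function(bases) bases %in% c("A", "C", "G", "T")
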