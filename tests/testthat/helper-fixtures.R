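# Small shared fixtures, all built in code.

# Four-taxon tree: two sexual/asexual pairs.
small_tree <- function(tip_len = 0.02, inner_len = 0.05) {
  nwk <- sprintf(
    "((s1:%1$f,a1:%1$f):%2$f,(s2:%1$f,a2:%1$f):%2$f);",
    tip_len, inner_len
  )
  annotated_tree(
    ape::read.tree(text = nwk),
    tibble::tibble(
      tip = c("s1", "a1", "s2", "a2"),
      mode = c("sexual", "asexual", "sexual", "asexual"),
      pair_id = c(1L, 1L, 2L, 2L)
    )
  )
}

# Two-taxon tree (one pair), for pairwise oracles.
two_taxon_tree <- function(len = 0.1) {
  annotated_tree(
    ape::read.tree(text = sprintf("(s1:%f,a1:%f);", len, len)),
    tibble::tibble(
      tip = c("s1", "a1"), mode = c("sexual", "asexual"), pair_id = c(1L, 1L)
    )
  )
}

aln_from <- function(gene_id, ...) {
  codon_alignment(gene_id, c(...))
}

# Independent translation oracle built directly on Biostrings' code table
# (string handling deliberately different from the package's machinery).
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Memoised small pipeline run shared across test files.
.run_cache <- new.env(parent = emptyenv())
small_run <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- pipeline_config(
      "timema-like",
      n_genes = 12, codons_per_gene = 40, seed = seed,
      B_anova = 99, B_boot = 99, utr_length = 60
    )
    .run_cache[[key]] <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  }
  .run_cache[[key]]
}
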