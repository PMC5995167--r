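#' In-frame codon alignment for one gene
#'
#' A light container for one gene's aligned coding sequences across taxa.
#' Sequences must be equal-length, in frame (length divisible by 3, reading
#' frame starting at the first column) and free of internal stop codons in
#' their ungapped reading.
#'
#' @param gene_id Gene identifier (single string).
#' @param seqs Named character vector (or named list) of aligned sequences
#'   over `A`,`C`,`G`,`T`,`-` (ambiguity codes are tolerated but excluded
#'   from most statistics); names are taxa.
#' @return An object of class `codon_aln` with fields `gene_id`, `taxa`,
#'   `seqs`, `n_codons`.
#' @export
codon_alignment <- function(gene_id, seqs) {
  check_string(gene_id, "gene_id")
  seqs <- toupper(unlist(seqs))
  taxa <- names(seqs)
  if (is.null(taxa) || anyDuplicated(taxa) || any(taxa == "")) {
    abort("sequences must carry unique taxon names", class = "asexdiv_input")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("all sequences in an alignment must have equal length", class = "asexdiv_input")
  }
  if (lens[[1L]] %% 3L != 0L) {
    abort("alignment length must be divisible by 3", class = "asexdiv_frame")
  }
  code <- genetic_code()
  stops <- names(code)[code == "*"]
  for (tx in taxa) {
    ungapped <- gsub("-", "", seqs[[tx]], fixed = TRUE)
    if (nchar(ungapped) %% 3L == 0L && nchar(ungapped) > 0L) {
      cods <- split_codons(ungapped)
      if (any(cods %in% stops)) {
        abort(sprintf("internal stop codon in %s / %s", gene_id, tx),
          class = "asexdiv_input"
        )
      }
    }
  }
  structure(
    list(
      gene_id = gene_id, taxa = taxa, seqs = seqs,
      n_codons = lens[[1L]] %/% 3L
    ),
    class = "codon_aln"
  )
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf(
    "<codon_aln> %s: %d taxa x %d codons\n",
    x$gene_id, length(x$taxa), x$n_codons
  ))
  invisible(x)
}

#' Read and write codon alignments as FASTA
#'
#' Thin wrappers around Biostrings that enforce the codon-alignment
#' invariants on the way in and write wrapped (60-column), uppercased
#' records on the way out, so a round trip is byte-identical.
#'
#' @param path FASTA file path.
#' @param gene_id Gene id to attach; defaults to the file name without
#'   extension.
#' @return `read_codon_alignment()` returns a [codon_alignment()];
#'   `write_codon_alignment()` returns `path` invisibly.
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  gene_id <- gene_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  x <- Biostrings::readDNAStringSet(path)
  codon_alignment(gene_id, stats::setNames(as.character(x), names(x)))
}

#' @param aln A [codon_alignment()].
#' @rdname read_codon_alignment
#' @export
write_codon_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln$seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Species tree annotated with reproductive mode and pair membership
#'
#' Couples a rooted `phylo` tree with a per-tip metadata table assigning each
#' tip a reproductive `mode` (`"sexual"` or `"asexual"`) and a `pair_id`
#' linking each asexual lineage to its sexual sister species. Every pair must
#' contain exactly one sexual and one asexual tip.
#'
#' @param phylo A rooted `ape::phylo` object with branch lengths.
#' @param meta A data frame with columns `tip`, `mode`, `pair_id`.
#' @return An object of class `annotated_tree` with fields `phylo`, `meta`.
#' @export
annotated_tree <- function(phylo, meta) {
  if (!inherits(phylo, "phylo")) {
    abort("`phylo` must be an ape phylogeny", class = "asexdiv_input")
  }
  if (!ape::is.rooted(phylo)) {
    abort("tree must be rooted", class = "asexdiv_input")
  }
  if (is.null(phylo$edge.length) || any(phylo$edge.length < 0)) {
    abort("tree must have non-negative branch lengths", class = "asexdiv_input")
  }
  meta <- as_tibble(meta)
  need <- c("tip", "mode", "pair_id")
  if (!all(need %in% names(meta))) {
    abort("metadata needs columns tip, mode, pair_id", class = "asexdiv_input")
  }
  if (!setequal(meta$tip, phylo$tip.label)) {
    abort("metadata tips must match tree tips", class = "asexdiv_input")
  }
  if (!all(meta$mode %in% c("sexual", "asexual"))) {
    abort("mode must be 'sexual' or 'asexual'", class = "asexdiv_input")
  }
  chk <- dplyr::count(meta, .data$pair_id, .data$mode)
  if (any(chk$n != 1L) || !all(table(meta$pair_id) == 2L)) {
    abort("each pair_id needs exactly one sexual and one asexual tip",
      class = "asexdiv_input"
    )
  }
  structure(list(phylo = phylo, meta = meta), class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf(
    "<annotated_tree> %d tips, %d pairs\n",
    length(x$phylo$tip.label), dplyr::n_distinct(x$meta$pair_id)
  ))
  print(x$meta, n = Inf)
  invisible(x)
}

#' Read an annotated tree from newick plus a metadata sidecar
#'
#' @param newick_path Path to a rooted newick tree.
#' @param meta_path Path to a tab-separated table with columns `tip`, `mode`,
#'   `pair_id`.
#' @return An [annotated_tree()].
#' @export
read_annotated_tree <- function(newick_path, meta_path) {
  phylo <- ape::read.tree(newick_path)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  annotated_tree(phylo, meta)
}

#' @rdname read_annotated_tree
#' @param tree An [annotated_tree()].
#' @export
write_annotated_tree <- function(tree, newick_path, meta_path) {
  ape::write.tree(tree$phylo, newick_path)
  readr::write_tsv(tree$meta, meta_path)
  invisible(newick_path)
}

#' Default ten-species study tree
#'
#' A rooted ten-taxon tree of five sexual--asexual sister pairs of *Timema*
#' stick insects, with pair divergences increasing from the youngest
#' (*T. bartmani* / *T. tahoe*) to the oldest (*T. podura* /
#' *T. genevievae*) asexual lineage. Branch lengths are in expected
#' substitutions per site and are chosen to be realistic for transcriptome
#' divergence between these species, not estimated from data.
#'
#' @return An [annotated_tree()].
#' @examples
#' tr <- timema_tree()
#' tr$meta
#' @export
timema_tree <- function() {
  nwk <- paste0(
    "(((((Tbi:0.004,Tte:0.004):0.035,(Tce:0.006,Tms:0.006):0.033):0.02,",
    "(Tps:0.01,Tdi:0.01):0.045):0.02,(Tcm:0.016,Tsi:0.016):0.055):0.02,",
    "(Tpa:0.025,Tge:0.025):0.062);"
  )
  phylo <- ape::read.tree(text = nwk)
  meta <- tibble(
    tip = c("Tbi", "Tte", "Tce", "Tms", "Tps", "Tdi", "Tcm", "Tsi", "Tpa", "Tge"),
    mode = rep(c("sexual", "asexual"), 5),
    pair_id = rep(1:5, each = 2)
  )
  annotated_tree(phylo, meta)
}

#' Branch table of an annotated tree
#'
#' One row per edge of the rooted tree, labelling each branch by the label of
#' its child node (tip label for terminal branches, `"node<k>"` otherwise)
#' and annotating terminal branches with the tip's reproductive mode and pair.
#'
#' @param tree An [annotated_tree()].
#' @return A tibble with columns `edge_id`, `parent`, `child`, `branch`
#'   (child label), `length`, `terminal`, `mode` (`"internal"` for internal
#'   branches), `pair_id` (`NA` for internal branches).
#' @export
branch_table <- function(tree) {
  phylo <- tree$phylo
  ntip <- length(phylo$tip.label)
  lab <- node_labels(phylo)
  child <- phylo$edge[, 2L]
  out <- tibble(
    edge_id = seq_len(nrow(phylo$edge)),
    parent = phylo$edge[, 1L],
    child = child,
    branch = lab[child],
    length = phylo$edge.length,
    terminal = child <= ntip
  )
  out <- dplyr::left_join(out, tree$meta, by = c(branch = "tip"))
  out$mode <- dplyr::if_else(out$terminal, out$mode, "internal")
  out
}

node_labels <- function(phylo) {
  ntip <- length(phylo$tip.label)
  nnode <- phylo$Nnode
  c(phylo$tip.label, paste0("node", seq_len(nnode) + ntip))
}
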