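#' GC content at third codon positions (GC3)
#'
#' Third codon positions are largely free of protein-level constraint, so
#' their base composition tracks mutation and GC-biased gene conversion
#' rather than selection on the protein. Columns whose third-position base is
#' not one of A/C/G/T (gaps, ambiguity codes) are excluded from both
#' numerator and denominator.
#'
#' @param seq An in-frame coding sequence (single string, length divisible
#'   by 3). Vectorised over a character vector.
#' @return Fraction of G/C at third codon positions, in `[0, 1]`.
#' @examples
#' gc3("ATGGCC")
#' gc3("ATGGCCATA")
#' @export
gc3 <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      abort("empty sequence has no GC3", class = "asexdiv_input")
    }
    codons <- split_codons(s)
    third <- substr(codons, 3L, 3L)
    third <- third[is_acgt(third)]
    if (length(third) == 0L) {
      abort("no scorable third positions", class = "asexdiv_input")
    }
    mean(third %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of an arbitrary nucleotide region
#'
#' Used for untranslated regions (UTRs): a positive correlation between UTR
#' GC content and GC3 across genes indicates that composition is driven by a
#' region-wide force such as gBGC rather than by translational selection.
#'
#' @param seq Nucleotide string. Vectorised.
#' @param ambiguity `"skip"` drops non-ACGT characters; `"error"` aborts on
#'   them.
#' @return `(G + C) / length`, computed over retained characters.
#' @examples
#' gc_region("ATGC")
#' @export
gc_region <- function(seq, ambiguity = c("skip", "error")) {
  ambiguity <- match.arg(ambiguity)
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      abort("empty sequence has no GC content", class = "asexdiv_input")
    }
    bases <- split_bases(s)
    ok <- is_acgt(bases)
    if (!all(ok)) {
      if (ambiguity == "error") {
        abort("sequence contains non-ACGT characters", class = "asexdiv_input")
      }
      bases <- bases[ok]
      if (length(bases) == 0L) {
        abort("no scorable positions", class = "asexdiv_input")
      }
    }
    mean(bases %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Jukes--Cantor distance between two aligned sequences
#'
#' Columns containing a gap or ambiguity code in either sequence are removed
#' before computing the proportion `p` of differing columns; the distance is
#' the Jukes--Cantor correction `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return Distance (substitutions per site), with attributes
#'   `n_sites` (retained columns) and `p` (raw difference proportion).
#' @examples
#' jukes_cantor("ACGT", "ACGT")
#' jukes_cantor("AAAAAAAAAA", "AAAAAAAAAC")
#' @export
jukes_cantor <- function(seq_a, seq_b) {
  a <- split_bases(seq_a)
  b <- split_bases(seq_b)
  if (length(a) != length(b)) {
    abort("aligned sequences must have equal length", class = "asexdiv_input")
  }
  keep <- is_acgt(a) & is_acgt(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) {
    abort("no comparable columns after pairwise deletion", class = "asexdiv_input")
  }
  p <- mean(a != b)
  if (p >= 0.75) {
    abort(
      sprintf("difference proportion %.3f >= 3/4: Jukes-Cantor distance undefined (saturation)", p),
      class = "asexdiv_saturation"
    )
  }
  d <- -0.75 * log(1 - 4 * p / 3)
  structure(d, n_sites = length(a), p = p)
}

#' Rank species pairs by interspecific divergence
#'
#' Mean pairwise Jukes--Cantor distance between the two members of each
#' sexual--asexual species pair, across their shared genes, serves as a proxy
#' for the age of the asexual lineage. Pairs are ranked from youngest
#' (smallest mean distance) to oldest; ties are broken by `pair_id` so the
#' ordering is stable.
#'
#' @param alignments A list of [codon_alignment()] objects covering both
#'   members of each pair.
#' @param tree An [annotated_tree()] giving pair membership and modes.
#' @return A tibble with one row per pair: `pair_id`, the two species,
#'   `n_genes`, `n_saturated` (genes skipped because the distance was
#'   undefined), `mean_jc` and `rank` (1 = youngest).
#' @export
rank_pairs_by_divergence <- function(alignments, tree) {
  meta <- tree$meta
  pairs <- sort(unique(meta$pair_id))
  res <- purrr::map_dfr(pairs, function(pid) {
    sx <- meta$tip[meta$pair_id == pid & meta$mode == "sexual"]
    ax <- meta$tip[meta$pair_id == pid & meta$mode == "asexual"]
    ds <- purrr::map(alignments, function(aln) {
      if (!all(c(sx, ax) %in% aln$taxa)) {
        return(NULL)
      }
      tryCatch(
        as.numeric(jukes_cantor(aln$seqs[[sx]], aln$seqs[[ax]])),
        asexdiv_saturation = function(e) NA_real_
      )
    })
    ds <- unlist(ds)
    if (length(ds) == 0L) {
      abort(sprintf("no genes cover pair %s", pid), class = "asexdiv_input")
    }
    n_sat <- sum(is.na(ds))
    if (n_sat > 0L) {
      inform(sprintf("pair %s: %d gene(s) skipped (saturated)", pid, n_sat))
    }
    tibble(
      pair_id = pid, sexual = sx, asexual = ax,
      n_genes = sum(!is.na(ds)), n_saturated = n_sat,
      mean_jc = mean(ds, na.rm = TRUE)
    )
  })
  res <- dplyr::arrange(res, .data$mean_jc, .data$pair_id)
  res$rank <- seq_len(nrow(res))
  res
}
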