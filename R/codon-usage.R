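#' Count sense codons in a coding sequence
#'
#' @param x A coding sequence (string) or a named numeric vector of codon
#'   counts (names are codons).
#' @param code Genetic code.
#' @return Named integer vector over all sense codons of `code`.
#' @export
count_codons <- function(x, code = genetic_code()) {
  sense <- sense_codons(code)
  if (is.character(x) && length(x) == 1L) {
    codons <- split_codons(gsub("-", "", x, fixed = TRUE))
    codons <- codons[codons %in% sense]
    tab <- table(factor(codons, levels = sense))
    return(stats::setNames(as.integer(tab), sense))
  }
  if (!is.null(names(x))) {
    out <- stats::setNames(rep(0, length(sense)), sense)
    hit <- intersect(names(x), sense)
    out[hit] <- as.numeric(x[hit])
    return(out)
  }
  abort("`x` must be a sequence string or named codon counts", class = "asexdiv_input")
}

# Amino-acid degeneracy classes of a code: number of synonymous codons per
# amino acid (stop excluded).
aa_family_sizes <- function(code = genetic_code()) {
  tab <- table(code[code != "*"])
  stats::setNames(as.integer(tab), names(tab))
}

#' Effective number of codons (Enc)
#'
#' Wright's estimator of codon usage bias. For each amino acid with `n >= 2`
#' observations and codon usage fractions `p_i`, the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; `F` is averaged within degeneracy
#' classes (2-, 3-, 4- and 6-fold amino acids; the 6-fold amino acids Leu,
#' Ser and Arg are kept as their own class) and
#' `Enc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to `[20, 61]`. Enc is 20
#' when every amino acid uses a single codon exclusively and 61 under equal
#' use of all synonymous codons. When no 3-fold amino acid is observed,
#' `F3` is imputed as `(F2 + F4)/2` (Wright's convention); if any other
#' class is entirely missing the estimate is undefined (`NA`, flagged via
#' attribute `"flag"`).
#'
#' @param x Coding sequence or named codon counts (see [count_codons()]).
#' @param code Genetic code.
#' @return Enc value in `[20, 61]`, or `NA` when undefined.
#' @examples
#' # one codon per amino acid, every class observed: maximal bias
#' code <- genetic_code()
#' cassette <- paste0(
#'   vapply(unique(code[code != "*"]), function(a) names(code)[code == a][1], ""),
#'   collapse = ""
#' )
#' enc(strrep(cassette, 10))
#' @export
enc <- function(x, code = genetic_code()) {
  counts <- count_codons(x, code)
  if (sum(counts) < 1) {
    abort("need at least one sense codon", class = "asexdiv_input")
  }
  fam <- aa_family_sizes(code)
  aa_of <- code[names(counts)]
  f_by_aa <- vapply(names(fam), function(aa) {
    ni <- counts[aa_of == aa]
    n <- sum(ni)
    if (n < 2) {
      return(NA_real_)
    }
    p <- ni / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  class_of <- fam[names(f_by_aa)]
  fbar <- function(k) {
    v <- f_by_aa[class_of == k & !is.na(f_by_aa)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- fbar(2L)
  f3 <- fbar(3L)
  f4 <- fbar(4L)
  f6 <- fbar(6L)
  n_aa <- c(`2` = sum(fam == 2L), `3` = sum(fam == 3L), `4` = sum(fam == 4L), `6` = sum(fam == 6L))
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) <= 0)) {
    return(structure(NA_real_, flag = "undefined: missing or degenerate degeneracy class"))
  }
  val <- sum(fam == 1L) + n_aa[["2"]] / f2 + n_aa[["3"]] / f3 +
    n_aa[["4"]] / f4 + n_aa[["6"]] / f6
  unname(min(max(val, 20), 61))
}

#' Positional nucleotide composition of a codon usage vector
#'
#' GC and purine (A/G) content at each of the three codon positions, weighted
#' by codon usage.
#'
#' @param usage Named numeric vector of codon frequencies or counts.
#' @return A list with numeric length-3 vectors `gc` and `purine`.
#' @export
positional_composition <- function(usage) {
  usage <- usage / sum(usage)
  codons <- names(usage)
  gc <- numeric(3L)
  pur <- numeric(3L)
  for (i in 1:3) {
    b <- substr(codons, i, i)
    gc[i] <- sum(usage[b %in% c("G", "C")])
    pur[i] <- sum(usage[b %in% c("A", "G")])
  }
  list(gc = gc, purine = pur)
}

#' Expected codon usage from positional GC and purine content
#'
#' Under the composition-only null model, the probability of base `b` at
#' codon position `i` factorises the position's GC share `g_i` and purine
#' share `a_i`: `P(G) = g a`, `P(C) = g (1 - a)`, `P(A) = (1 - g) a`,
#' `P(T) = (1 - g)(1 - a)`. The expected usage of a codon is the product
#' over its three positions, renormalised over the sense codons of the code.
#' Degenerate compositions are floored at `eps` before renormalising.
#'
#' @param gc,purine Numeric length-3 vectors of per-position GC and purine
#'   shares.
#' @param code Genetic code.
#' @param eps Composition floor.
#' @return Named numeric vector of expected sense-codon frequencies (sums
#'   to 1).
#' @export
expected_codon_usage <- function(gc, purine, code = genetic_code(), eps = 1e-6) {
  base_p <- function(g, a) {
    p <- c(A = (1 - g) * a, C = g * (1 - a), G = g * a, T = (1 - g) * (1 - a))
    p <- pmax(p, eps)
    p / sum(p)
  }
  P <- lapply(1:3, function(i) base_p(gc[i], purine[i]))
  sense <- sense_codons(code)
  e <- vapply(sense, function(cod) {
    b <- strsplit(cod, "")[[1L]]
    P[[1L]][[b[1L]]] * P[[2L]][[b[2L]]] * P[[3L]][[b[3L]]]
  }, numeric(1))
  e / sum(e)
}

#' Codon deviation coefficient (CDC)
#'
#' Measures how far observed codon usage deviates from the usage expected
#' from the gene's own background nucleotide composition, making the value
#' comparable across species with different GC content. The expected usage
#' is built from the observed per-position GC and purine contents via
#' [expected_codon_usage()], then renormalised within each amino-acid
#' family so that amino-acid usage itself does not contribute; the CDC is
#' the cosine distance `1 - cos(observed, expected)` between the two
#' codon-frequency vectors, which lies in `[0, 1]` (0 = usage fully
#' explained by composition; values near 1 = maximal deviation, i.e.
#' effective selection on codon usage).
#'
#' @param x Coding sequence or named codon counts.
#' @param code Genetic code.
#' @param eps Floor applied to degenerate base compositions.
#' @return CDC value in `[0, 1]`.
#' @export
cdc <- function(x, code = genetic_code(), eps = 1e-6) {
  counts <- count_codons(x, code)
  if (sum(counts) < 1) {
    abort("need at least one sense codon", class = "asexdiv_input")
  }
  obs <- counts / sum(counts)
  comp <- positional_composition(obs)
  e_raw <- expected_codon_usage(comp$gc, comp$purine, code, eps)
  aa_of <- code[names(obs)]
  expected <- obs * 0
  for (aa in unique(aa_of)) {
    fam <- aa_of == aa
    aa_freq <- sum(obs[fam])
    denom <- sum(e_raw[fam])
    expected[fam] <- if (denom > 0) aa_freq * e_raw[fam] / denom else 0
  }
  cosine <- sum(obs * expected) /
    sqrt(sum(obs^2) * sum(expected^2))
  min(max(1 - cosine, 0), 1)
}

#' Per-gene codon usage table
#'
#' Computes Enc, CDC and GC3 for every gene x species in a set of
#' alignments.
#'
#' @param alignments Named list of [codon_alignment()] objects.
#' @param code Genetic code.
#' @return A tibble with columns `gene`, `species`, `enc`, `cdc`, `gc3`,
#'   `n_codons`.
#' @export
codon_usage_table <- function(alignments, code = genetic_code()) {
  purrr::map_dfr(alignments, function(aln) {
    purrr::map_dfr(aln$taxa, function(tx) {
      s <- gsub("-", "", aln$seqs[[tx]], fixed = TRUE)
      tibble(
        gene = aln$gene_id, species = tx,
        enc = as.numeric(enc(s, code)), cdc = cdc(s, code),
        gc3 = gc3(s), n_codons = nchar(s) %/% 3L
      )
    })
  })
}
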