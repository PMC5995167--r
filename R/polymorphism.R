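#' Filter pooled-read pileup sites into SNP calls
#'
#' Applies the standard pooled-sequencing filters: a site is kept when its
#' coverage (sum of base counts) is at least `min_coverage`, its
#' minor-allele read fraction is at least `min_maf`, its mean base quality
#' is at least `min_phred`, and exactly one alternate allele exceeds the
#' frequency floor (tri-allelic sites are dropped and logged). Kept sites
#' are annotated with their codon context in the reference open reading
#' frame and classified as synonymous or nonsynonymous.
#'
#' @param sites Pileup tibble with columns `gene`, `pos` (0-based within the
#'   ORF), `ref`, `A`, `C`, `G`, `T`, `mean_phred`, optionally `species`.
#' @param ref_seqs Named character vector of reference ORFs (names are gene
#'   ids).
#' @param min_coverage,min_maf,min_phred Filter thresholds; the defaults are
#'   the conventional pooled-RNA values (20x coverage, 10% minor allele
#'   frequency, mean phred 20).
#' @param code Genetic code.
#' @return A tibble of SNP records: `species` (if present), `gene`, `pos`,
#'   `codon_index` (0-based), `codon_position` (1-3), `ref_codon`, `ref`,
#'   `alt`, `maf`, `coverage`, `mean_phred`, `effect`, `fold`,
#'   `creates_stop`. A filtering log (counts per rejection reason) is
#'   attached as attribute `"log"`.
#' @export
filter_snps <- function(sites, ref_seqs, min_coverage = 20, min_maf = 0.10,
                        min_phred = 20, code = genetic_code()) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0L) {
    out <- sites
    attr(out, "log") <- c(low_coverage = 0L, low_maf = 0L, low_phred = 0L, triallelic = 0L, no_alt = 0L)
    return(out)
  }
  lens <- nchar(ref_seqs)
  bad_pos <- sites$pos < 0L | sites$pos >= lens[sites$gene] | is.na(lens[sites$gene])
  if (any(bad_pos)) {
    abort("pileup position outside the reference ORF", class = "asexdiv_structure")
  }
  cnt <- as.matrix(sites[, c("A", "C", "G", "T")])
  coverage <- rowSums(cnt)
  ref_idx <- match(sites$ref, colnames(cnt))
  ref_n <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), ref_idx)] <- 0L
  alt_freq <- alt_cnt / pmax(coverage, 1L)
  n_above <- rowSums(alt_freq >= min_maf)
  alt_idx <- max.col(alt_cnt, ties.method = "first")
  alt_base <- colnames(cnt)[alt_idx]
  alt_n <- alt_cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  maf <- pmin(alt_n, coverage - alt_n) / pmax(coverage, 1L)

  pass_cov <- coverage >= min_coverage
  pass_phred <- sites$mean_phred >= min_phred
  biallelic <- n_above == 1L
  triallelic <- n_above >= 2L
  pass_maf <- maf >= min_maf
  keep <- pass_cov & pass_phred & biallelic & pass_maf
  log <- c(
    low_coverage = sum(!pass_cov),
    low_maf = sum(pass_cov & pass_phred & biallelic & !pass_maf),
    low_phred = sum(pass_cov & !pass_phred),
    triallelic = sum(triallelic),
    no_alt = sum(n_above == 0L & alt_n == 0L)
  )
  out <- sites[keep, , drop = FALSE]
  out$alt <- alt_base[keep]
  out$maf <- maf[keep]
  out$coverage <- coverage[keep]
  out$codon_index <- out$pos %/% 3L
  out$codon_position <- out$pos %% 3L + 1L
  out$ref_codon <- substr(
    ref_seqs[out$gene], out$codon_index * 3L + 1L, out$codon_index * 3L + 3L
  )
  eff <- classify_snp_effect(out$ref_codon, out$codon_position, out$alt, code)
  out$effect <- eff$effect
  out$fold <- eff$fold
  out$creates_stop <- eff$creates_stop
  skipped <- is.na(out$effect)
  if (any(skipped)) {
    inform(sprintf("%d SNP(s) skipped: reference codon not a sense codon", sum(skipped)))
    out <- out[!skipped, , drop = FALSE]
  }
  cols <- intersect(
    c(
      "species", "gene", "pos", "codon_index", "codon_position", "ref_codon",
      "ref", "alt", "maf", "coverage", "mean_phred", "effect", "fold",
      "creates_stop"
    ),
    names(out)
  )
  out <- out[, cols]
  attr(out, "log") <- log
  out
}

#' Classify the coding effect of a single-nucleotide variant
#'
#' Substitutes `alt` at the given codon position of the reference codon and
#' compares the encoded amino acids: synonymous when identical, otherwise
#' nonsynonymous. Variants creating a stop codon are nonsynonymous and
#' flagged. The fold degeneracy class of the site (1-4) is reported from
#' [codon_degeneracy()].
#'
#' @param ref_codon Sense codon(s) (vectorised).
#' @param codon_position Position within the codon, 1-3.
#' @param alt Alternate base.
#' @param code Genetic code.
#' @return A tibble with columns `effect` (`"synonymous"`/`"nonsynonymous"`,
#'   `NA` for non-sense reference codons), `fold`, `creates_stop`.
#' @export
classify_snp_effect <- function(ref_codon, codon_position, alt, code = genetic_code()) {
  ref_codon <- toupper(ref_codon)
  alt <- toupper(alt)
  n <- length(ref_codon)
  mut <- ref_codon
  substr(mut, codon_position, codon_position) <- alt
  valid <- ref_codon %in% sense_codons(code) & alt %in% BASES
  ref_aa <- ifelse(valid, code[ref_codon], NA_character_)
  mut_aa <- ifelse(valid, code[mut], NA_character_)
  creates_stop <- !is.na(mut_aa) & mut_aa == "*"
  effect <- as.character(ifelse(
    !valid, NA_character_,
    ifelse(!creates_stop & ref_aa == mut_aa, "synonymous", "nonsynonymous")
  ))
  deg <- codon_degeneracy(code)
  fold <- ifelse(valid, deg[cbind(match(ref_codon, CODONS), codon_position)], NA_integer_)
  tibble(effect = effect, fold = as.integer(fold), creates_stop = creates_stop)
}

#' pN, pS and their ratio per gene
#'
#' Counts of filtered nonsynonymous and synonymous SNPs per gene, normalised
#' by the gene's Nei--Gojobori nonsynonymous and synonymous site counts
#' (see [ng86_sites()]): `pN = n_nonsyn / N_sites`, `pS = n_syn / S_sites`.
#' The ratio is `NA` when `pS = 0`. With `normalize = FALSE` the raw SNP
#' counts are used instead of site-normalised rates.
#'
#' @param snps SNP records from [filter_snps()].
#' @param ref_seqs Named character vector of reference ORFs.
#' @param code Genetic code.
#' @param normalize Site-normalise (default) or use raw counts.
#' @return A tibble with one row per (`species` if present, `gene`):
#'   `n_nonsyn`, `n_syn`, `N_sites`, `S_sites`, `pn`, `ps`, `pn_ps`.
#' @export
pnps_per_gene <- function(snps, ref_seqs, code = genetic_code(), normalize = TRUE) {
  if (any(nchar(ref_seqs) == 0L)) {
    abort("zero-length reference gene", class = "asexdiv_input")
  }
  sites <- purrr::map_dfr(names(ref_seqs), function(g) {
    s <- ng86_sites(ref_seqs[[g]], code)
    tibble(gene = g, N_sites = s[["N_sites"]], S_sites = s[["S_sites"]])
  })
  keys <- intersect(c("species", "gene"), names(snps))
  counts <- dplyr::summarise(
    dplyr::group_by(snps, dplyr::across(dplyr::all_of(keys))),
    n_nonsyn = sum(.data$effect == "nonsynonymous"),
    n_syn = sum(.data$effect == "synonymous"),
    .groups = "drop"
  )
  grid <- if ("species" %in% keys) {
    tidyr::expand_grid(species = unique(snps$species), gene = names(ref_seqs))
  } else {
    tibble(gene = names(ref_seqs))
  }
  out <- dplyr::left_join(grid, counts, by = keys)
  out$n_nonsyn[is.na(out$n_nonsyn)] <- 0L
  out$n_syn[is.na(out$n_syn)] <- 0L
  out <- dplyr::left_join(out, sites, by = "gene")
  if (normalize) {
    out$pn <- out$n_nonsyn / out$N_sites
    out$ps <- ifelse(out$S_sites > 0, out$n_syn / out$S_sites, NA_real_)
  } else {
    out$pn <- as.numeric(out$n_nonsyn)
    out$ps <- as.numeric(out$n_syn)
  }
  out$pn_ps <- ifelse(!is.na(out$ps) & out$ps > 0, out$pn / out$ps, NA_real_)
  out
}

#' Population polymorphism summary per species
#'
#' The two headline quantities of a pooled-population comparison: the
#' fraction of genes ("transcripts") carrying at least one filtered SNP,
#' and, among genes with SNPs, the per-gene proportion of variable sites
#' (SNPs divided by ungapped ORF length), summarised by its median with a
#' seeded percentile-bootstrap confidence interval.
#'
#' @param snps SNP records from [filter_snps()] (must carry `species`).
#' @param gene_universe Character vector of all genes screened (fixed across
#'   species).
#' @param ref_lengths Named integer vector of ungapped ORF lengths (nt).
#' @param B Bootstrap replicates (default 5000).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap.
#' @param species Species to report (defaults to those present in `snps`;
#'   pass the full tip set so species without any SNP get a zero row).
#' @return A tibble with one row per species: `n_genes`, `n_with_snps`,
#'   `prop_with_snps`, `median_var_prop`, `var_prop_lo`, `var_prop_hi`.
#' @export
polymorphism_summary <- function(snps, gene_universe, ref_lengths,
                                 B = 5000L, level = 0.95, seed = 1L,
                                 species = sort(unique(snps$species))) {
  if (length(gene_universe) == 0L) {
    abort("empty gene universe", class = "asexdiv_input")
  }
  purrr::map_dfr(species, function(sp) {
    d <- dplyr::filter(snps, .data$species == sp, .data$gene %in% gene_universe)
    per_gene <- dplyr::count(d, .data$gene, name = "n_snps")
    per_gene$var_prop <- per_gene$n_snps / ref_lengths[per_gene$gene]
    n_with <- nrow(per_gene)
    if (n_with >= 2L) {
      ci <- bootstrap_ci(per_gene$var_prop,
        statistic = "median", B = B,
        level = level, seed = substream_seed(seed, "poly", sp)
      )
      med <- stats::median(per_gene$var_prop)
      lo <- ci$lower
      hi <- ci$upper
    } else if (n_with == 1L) {
      med <- per_gene$var_prop
      lo <- med
      hi <- med
    } else {
      med <- NA_real_
      lo <- NA_real_
      hi <- NA_real_
    }
    tibble(
      species = sp, n_genes = length(gene_universe), n_with_snps = n_with,
      prop_with_snps = n_with / length(gene_universe),
      median_var_prop = med, var_prop_lo = lo, var_prop_hi = hi
    )
  })
}

#' Read and write pileup tables
#'
#' The pileup dialect is a TSV with columns `species` (optional), `gene`,
#' `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `mean_phred`.
#'
#' @param path File path.
#' @return A tibble of pileup sites.
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_pileup_tsv
#' @param sites Pileup tibble.
#' @export
write_pileup_tsv <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' Read SNP candidate sites from a minimal VCF
#'
#' Accepts an uncompressed VCF 4.x file in which `CHROM` is a gene id and
#' `POS` is 1-based within the gene's ORF. Depth and allelic depth are taken
#' from the INFO keys `DP` and `AD` (comma-separated ref,alt counts); the
#' `QUAL` column is used as the mean base quality. Records without `AD` get
#' the full depth assigned to the reference allele.
#'
#' @param path VCF file path.
#' @return A pileup-site tibble as consumed by [filter_snps()].
#' @export
read_snp_vcf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || !startsWith(lines[1L], "#CHROM")) {
    abort("not a VCF: missing #CHROM header", class = "asexdiv_input")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (length(m) == 0L) {
      return(NA_character_)
    }
    sub(paste0("^;?", key, "="), "", m)
  }
  purrr::map_dfr(fields, function(f) {
    ref <- toupper(f[4L])
    alt <- toupper(f[5L])
    info <- f[8L]
    dp <- suppressWarnings(as.integer(get_info(info, "DP")))
    ad <- get_info(info, "AD")
    if (!is.na(ad)) {
      parts <- as.integer(strsplit(ad, ",", fixed = TRUE)[[1L]])
      ref_n <- parts[1L]
      alt_n <- if (length(parts) > 1L) parts[2L] else 0L
    } else {
      ref_n <- dp %||% 0L
      alt_n <- 0L
    }
    counts <- stats::setNames(rep(0L, 4L), BASES)
    if (ref %in% BASES) counts[ref] <- ref_n
    if (alt %in% BASES) counts[alt] <- counts[alt] + alt_n
    tibble(
      gene = f[1L], pos = as.integer(f[2L]) - 1L, ref = ref,
      A = counts[["A"]], C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
      mean_phred = suppressWarnings(as.numeric(f[6L]))
    )
  })
}
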