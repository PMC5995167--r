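mk_site <- function(gene = "g1", pos = 2L, ref = "G", alt = "A",
                    depth = 25L, alt_n = 5L, phred = 30) {
  counts <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
  counts[ref] <- depth - alt_n
  counts[alt] <- counts[alt] + alt_n
  tibble::tibble(
    gene = gene, pos = pos, ref = ref,
    A = counts[["A"]], C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
    mean_phred = phred
  )
}

ref1 <- c(g1 = "ATGGGGAAA") # Met Gly Lys

test_that("SNP filters apply the coverage, MAF and phred thresholds", {
  # coverage 19, MAF 0.5, phred 30 -> rejected
  expect_equal(nrow(filter_snps(mk_site(depth = 19L, alt_n = 9L), ref1)), 0L)
  # coverage 25, MAF 0.09 (rounded below), phred 30 -> rejected
  expect_equal(nrow(filter_snps(mk_site(depth = 100L, alt_n = 9L), ref1)), 0L)
  # coverage 25, MAF 0.20, phred 30 -> retained
  kept <- filter_snps(mk_site(depth = 25L, alt_n = 5L), ref1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$maf, 0.2)
  expect_equal(kept$codon_position, 3L)
  expect_equal(unname(kept$ref_codon), "ATG")
  expect_equal(kept$effect, "nonsynonymous") # ATG -> ATA (Met -> Ile)
  # phred below 20 -> rejected
  expect_equal(nrow(filter_snps(mk_site(phred = 19.5), ref1)), 0L)
  # tri-allelic site dropped and logged
  tri <- mk_site(depth = 30L, alt_n = 0L)
  tri$A <- 10L
  tri$T <- 10L
  tri$G <- 10L
  out <- filter_snps(tri, ref1)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "log")[["triallelic"]], 1L)
  # position outside the ORF is a structural error
  expect_error(
    filter_snps(mk_site(pos = 9L), ref1),
    class = "asexdiv_structure"
  )
})

test_that("filtering is monotone in all three thresholds", {
  withr::with_seed(6, {
    sites <- dplyr::bind_rows(lapply(1:200, function(i) {
      mk_site(
        pos = sample(0:8, 1), ref = "G",
        alt = sample(c("A", "C", "T"), 1),
        depth = sample(5:60, 1), alt_n = 0L, phred = runif(1, 10, 40)
      )
    }))
    # rebuild alt counts from scratch for a mix of frequencies
    sites$A <- 0L
    freq <- runif(200, 0, 0.6)
    depth <- sites$G
    alt_n <- rbinom(200, depth, freq)
    sites$G <- depth - alt_n
    sites$A <- alt_n
  })
  base_keep <- filter_snps(sites, ref1)
  for (args in list(
    list(min_coverage = 30), list(min_maf = 0.2), list(min_phred = 30)
  )) {
    stricter <- do.call(filter_snps, c(list(sites, ref1), args))
    expect_true(all(
      paste(stricter$gene, stricter$pos) %in% paste(base_keep$gene, base_keep$pos)
    ))
  }
})

test_that("SNP effect classification matches exhaustive translation", {
  code <- genetic_code()
  for (codon in sense_codons(code)) {
    for (pos in 1:3) {
      for (alt in c("A", "C", "G", "T")) {
        got <- classify_snp_effect(codon, pos, alt, code)
        mut <- codon
        substr(mut, pos, pos) <- alt
        aa_ref <- oracle_translate(codon)
        aa_mut <- oracle_translate(mut)
        want <- if (aa_mut == aa_ref && aa_mut != "*") "synonymous" else "nonsynonymous"
        expect_identical(got$effect, want)
        expect_identical(got$creates_stop, aa_mut == "*")
      }
    }
  }
})

test_that("effect classification covers the canonical examples", {
  g <- classify_snp_effect("GGG", 3, "A")
  expect_equal(g$effect, "synonymous")
  expect_equal(g$fold, 4L)
  m <- classify_snp_effect("ATG", 3, "A")
  expect_equal(m$effect, "nonsynonymous")
  w <- classify_snp_effect("TGG", 2, "A")
  expect_equal(w$effect, "nonsynonymous")
  expect_true(w$creates_stop)
})

test_that("Nei-Gojobori site counts match a brute-force enumeration", {
  oracle_sites <- function(seq) {
    codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
    S <- 0
    for (codon in codons) {
      for (pos in 1:3) {
        for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
          mut <- codon
          substr(mut, pos, pos) <- alt
          if (oracle_translate(mut) != "*" &&
            oracle_translate(mut) == oracle_translate(codon)) {
            S <- S + 1 / 3
          }
        }
      }
    }
    c(N = 3 * length(codons) - S, S = S)
  }
  withr::with_seed(12, {
    for (i in 1:10) {
      s <- paste0(asexdiv:::sim_root_codons(20, runif(1, 0.3, 0.7)), collapse = "")
      got <- ng86_sites(s)
      want <- oracle_sites(s)
      expect_equal(got[["N_sites"]], want[["N"]], tolerance = 1e-12)
      expect_equal(got[["S_sites"]], want[["S"]], tolerance = 1e-12)
      expect_equal(got[["N_sites"]] + got[["S_sites"]], 3 * got[["n_codons"]])
    }
  })
})

test_that("pN/pS per gene uses site-normalised counts", {
  ref <- c(gA = strrep("GGAATTCCA", 10)) # 30 codons
  snps <- tibble::tibble(
    gene = "gA",
    pos = c(2L, 3L), # one third-position, one first-position SNP
    codon_index = c(0L, 1L), codon_position = c(3L, 1L),
    ref_codon = c("GGA", "ATT"), ref = c("A", "A"), alt = c("G", "C"),
    maf = 0.2, coverage = 30L, mean_phred = 30,
    effect = c("synonymous", "nonsynonymous"),
    fold = c(4L, 1L), creates_stop = FALSE
  )
  out <- pnps_per_gene(snps, ref)
  sites <- ng86_sites(ref[["gA"]])
  expect_equal(out$pn, 1 / sites[["N_sites"]])
  expect_equal(out$ps, 1 / sites[["S_sites"]])
  expect_equal(out$pn_ps, (1 / sites[["N_sites"]]) / (1 / sites[["S_sites"]]))
  # raw-count mode
  raw <- pnps_per_gene(snps, ref, normalize = FALSE)
  expect_equal(raw$pn_ps, 1)
  # no SNPs: zero rates, undefined ratio
  none <- pnps_per_gene(snps[0, ], ref)
  expect_equal(none$pn, 0)
  expect_true(is.na(none$pn_ps))
  # all-Met gene has no synonymous sites: pS undefined
  met <- pnps_per_gene(snps[0, ], c(gM = strrep("ATG", 10)))
  expect_true(is.na(met$ps))
  expect_true(is.na(met$pn_ps))
  expect_error(pnps_per_gene(snps, c(gA = "")), class = "asexdiv_input")
})

test_that("polymorphism summaries cover edge cases", {
  lens <- c(g1 = 300L, g2 = 300L)
  empty <- tibble::tibble(species = character(), gene = character())
  out <- polymorphism_summary(empty, names(lens), lens,
    B = 50, species = c("sp1")
  )
  expect_equal(out$prop_with_snps, 0)
  expect_true(is.na(out$median_var_prop))
  expect_error(
    polymorphism_summary(empty, character(), lens, species = "sp1"),
    class = "asexdiv_input"
  )
  # constant per-gene proportions give a zero-width bootstrap interval
  snps <- tibble::tibble(
    species = "sp1", gene = rep(c("g1", "g2"), each = 3)
  )
  out <- polymorphism_summary(snps, names(lens), lens, B = 200, seed = 4)
  expect_equal(out$n_with_snps, 2L)
  expect_equal(out$median_var_prop, 0.01)
  expect_equal(out$var_prop_lo, out$var_prop_hi)
})

test_that("the minimal VCF reader feeds the SNP filter", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##source=unit-test",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "g1\t3\t.\tG\tA\t35\tPASS\tDP=40;AD=30,10",
    "g1\t7\t.\tA\tT\t15\tPASS\tDP=40;AD=30,10"
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  sites <- read_snp_vcf(f)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$pos, c(2L, 6L)) # POS is 1-based, sites are 0-based
  kept <- filter_snps(sites, ref1)
  expect_equal(nrow(kept), 1L) # second record fails the phred filter
  expect_equal(kept$maf, 0.25)
})
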