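test_that("root sampling hits the target GC3 and avoids stops", {
  withr::with_seed(1, {
    cods <- asexdiv:::sim_root_codons(500, 1 - 1e-12)
    expect_true(all(substr(cods, 3, 3) %in% c("G", "C")))
    expect_false(any(genetic_code()[cods] == "*"))
    big <- asexdiv:::sim_root_codons(1e5, 0.5)
    se <- sqrt(0.25 / 1e5)
    expect_lt(abs(mean(substr(big, 3, 3) %in% c("G", "C")) - 0.5), 3 * se)
  })
  cfg <- sim_config(n_genes = 1, codons_per_gene = 30, seed = 9)
  expect_identical(simulate_root(cfg, "g1"), simulate_root(cfg, "g1"))
  expect_false(identical(simulate_root(cfg, "g1"), simulate_root(cfg, "g2")))
  expect_error(sim_config(root_gc3 = 1.2), class = "asexdiv_config")
  expect_error(sim_config(root_gc3 = 0), class = "asexdiv_config")
  expect_error(sim_config(kappa = -1), class = "asexdiv_config")
})

test_that("branch evolution respects limits of its parameters", {
  seq0 <- strrep("ATGGCATTAGGC", 25)
  # zero branch length: identity
  out <- evolve_branch(seq0, 0, omega = 0.2, seed = 4)
  expect_equal(as.character(out), seq0)
  expect_equal(nrow(attr(out, "events")), 0L)
  # omega = 0: no nonsynonymous events on a long branch
  out <- evolve_branch(seq0, 2, omega = 0, seed = 4)
  ev <- attr(out, "events")
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$synonymous))
  # strong gBGC raises GC3 relative to the unbiased control
  g_b <- mean(vapply(1:5, function(i) {
    gc3(as.character(evolve_branch(seq0, 3, omega = 0.2, gbgc_b = 5, seed = i)))
  }, 0))
  g_0 <- mean(vapply(1:5, function(i) {
    gc3(as.character(evolve_branch(seq0, 3, omega = 0.2, gbgc_b = 0, seed = i)))
  }, 0))
  expect_gt(g_b, g_0)
  # no stops ever
  out <- evolve_branch(seq0, 5, omega = 1, seed = 99)
  expect_silent(codon_alignment("chk", c(x = as.character(out))))
})

test_that("gene simulation bookkeeping matches the sequences", {
  tree <- two_taxon_tree(len = 0.05)
  cfg <- sim_config(
    tree = tree, n_genes = 1, codons_per_gene = 200, seed = 21,
    utr_length = 0, gene_bias_sd = 0
  )
  sim <- simulate_gene(cfg, "g0001")
  aln <- sim$alignment
  expect_setequal(aln$taxa, c("s1", "a1"))
  # each substitution in the truth log changed exactly one base; sites hit
  # once must show up as a tip difference along the two-branch path
  tr <- sim$truth
  nt_pos <- (tr$site - 1L) * 3L + tr$pos
  hits <- table(nt_pos)
  d <- hamming(aln$seqs[["s1"]], aln$seqs[["a1"]])
  # positions hit exactly once along the path must differ between the tips;
  # positions hit several times may have reverted
  expect_gte(d, sum(hits == 1L))
  expect_lte(d, sum(hits == 1L) + sum(hits > 1L))
  # zero-length tree: tips identical to each other
  cfg0 <- sim_config(
    tree = two_taxon_tree(len = 0), n_genes = 1,
    codons_per_gene = 50, seed = 3, utr_length = 0
  )
  sim0 <- simulate_gene(cfg0, "g0001")
  expect_equal(sim0$alignment$seqs[["s1"]], sim0$alignment$seqs[["a1"]])
  expect_equal(nrow(sim0$truth), 0L)
})

test_that("with b = 0 weak->strong and strong->weak counts balance", {
  cfg <- sim_config(
    tree = small_tree(tip_len = 0.1, inner_len = 0.1),
    n_genes = 60, codons_per_gene = 80, seed = 14,
    gbgc_sexual = 0, gbgc_asexual = 0, gbgc_internal = 0,
    gene_bias_sd = 0, utr_length = 0
  )
  truth <- dplyr::bind_rows(lapply(
    sprintf("g%04d", 1:60),
    function(g) simulate_gene(cfg, g)$truth
  ))
  syn <- truth[truth$synonymous, ]
  ws <- sum(syn$class == "ws")
  sw <- sum(syn$class == "sw")
  # symmetric rates: equal in expectation; allow 4 binomial SD
  expect_lt(abs(ws - sw), 4 * sqrt((ws + sw) * 0.25) + 1)
})

test_that("simulated pileups have the configured properties", {
  cfg <- sim_config(n_genes = 1, codons_per_gene = 300, seed = 8)
  seq0 <- simulate_root(cfg, "g1")
  pu <- simulate_pileup(seq0, "sexual", cfg, gene_id = "g1", species = "Tbi")
  expect_true(all(pu$sites$pos >= 0 & pu$sites$pos < nchar(seq0)))
  expect_true(all(rowSums(pu$sites[, c("A", "C", "G", "T")]) >= 1))
  # determinism
  pu2 <- simulate_pileup(seq0, "sexual", cfg, gene_id = "g1", species = "Tbi")
  expect_identical(pu$sites, pu2$sites)
  # true variant allele frequencies respect the floor
  expect_true(all(pu$truth$maf >= 0.1 & pu$truth$maf <= 0.5))
  # theta = 0: only sub-threshold noise sites, none survive the filters
  cfg0 <- sim_config(
    n_genes = 1, codons_per_gene = 300, seed = 8,
    theta_sexual = 0, theta_asexual = 0
  )
  pu0 <- simulate_pileup(seq0, "sexual", cfg0, gene_id = "g1", species = "Tbi")
  expect_equal(nrow(pu0$truth), 0L)
  kept <- filter_snps(pu0$sites, c(g1 = seq0))
  expect_equal(nrow(kept), 0L)
})

test_that("study simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 2, codons_per_gene = 30, seed = 33, utr_length = 30)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$alignments$g0001$seqs, s2$alignments$g0001$seqs)
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$utrs, s2$utrs)
})
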