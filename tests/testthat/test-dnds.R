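# Loop-based path enumeration oracle for observed differences between two
# codons: averages synonymous/nonsynonymous step counts over stop-free
# orderings, translating with the oracle table.
oracle_pair_counts <- function(c1, c2) {
  if (c1 == c2) {
    return(c(nd = 0, sd = 0))
  }
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffs <- which(b1 != b2)
  perms <- if (length(diffs) == 1) {
    list(diffs)
  } else if (length(diffs) == 2) {
    list(diffs, rev(diffs))
  } else {
    grid <- expand.grid(a = diffs, b = diffs, c = diffs)
    grid <- grid[apply(grid, 1, function(r) length(unique(r)) == 3), ]
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  nds <- c()
  sds <- c()
  for (ord in perms) {
    cur <- b1
    nd <- 0
    sd <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b2[p]
      if (oracle_translate(paste0(nxt, collapse = "")) == "*") {
        ok <- FALSE
        break
      }
      if (oracle_translate(paste0(cur, collapse = "")) ==
        oracle_translate(paste0(nxt, collapse = ""))) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (ok) {
      nds <- c(nds, nd)
      sds <- c(sds, sd)
    }
  }
  if (length(nds) == 0) {
    return(NULL)
  }
  c(nd = mean(nds), sd = mean(sds))
}

test_that("codon pair counting matches the path-enumeration oracle", {
  sense <- sense_codons()
  withr::with_seed(23, {
    pairs <- cbind(sample(sense, 150, TRUE), sample(sense, 150, TRUE))
  })
  # make sure multi-position pairs are represented
  pairs <- rbind(pairs, c("GGA", "CCT"), c("ATG", "TAC"), c("TTA", "CGC"))
  for (i in seq_len(nrow(pairs))) {
    got <- asexdiv:::codon_pair_counts(pairs[i, 1], pairs[i, 2])
    want <- oracle_pair_counts(pairs[i, 1], pairs[i, 2])
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("branch rates vanish on identical sequences and count single changes", {
  tree <- two_taxon_tree()
  s <- strrep("ATGGCATTA", 12)
  aln <- codon_alignment("g", c(s1 = s, a1 = s))
  r <- branch_dnds(aln, tree)
  expect_true(all(r$dN == 0 & r$dS == 0))
  expect_true(all(is.na(r$omega)))
  # one synonymous change on 100+ codons: dN = 0, omega = 0
  s2 <- sub("GCA", "GCG", s) # Ala GCA -> GCG, synonymous
  aln2 <- codon_alignment("g", c(s1 = s, a1 = s2))
  r2 <- branch_dnds(aln2, tree)
  expect_equal(sum(r2$Sd), 1)
  expect_equal(sum(r2$Nd), 0)
  expect_equal(sum(r2$dN), 0)
  expect_true(any(r2$omega == 0, na.rm = TRUE))
})

test_that("two-taxon branch totals equal direct pairwise NG86", {
  tree <- two_taxon_tree()
  withr::with_seed(41, {
    cods <- asexdiv:::sim_root_codons(150, 0.5)
    child <- cods
    # introduce single-position changes in 20 distinct codons
    nb <- codon_neighbors()
    idx <- sample(150, 20)
    for (i in idx) {
      opts <- nb$to[nb$from == child[i] & !nb$to_stop]
      child[i] <- sample(opts, 1)
    }
  })
  s1 <- paste0(cods, collapse = "")
  s2 <- paste0(child, collapse = "")
  aln <- codon_alignment("g", c(s1 = s1, a1 = s2))
  r <- branch_dnds(aln, tree)
  want_nd <- 0
  want_sd <- 0
  for (i in seq_along(cods)) {
    cnt <- oracle_pair_counts(cods[i], child[i])
    want_nd <- want_nd + cnt[["nd"]]
    want_sd <- want_sd + cnt[["sd"]]
  }
  expect_equal(sum(r$Nd), want_nd, tolerance = 1e-12)
  expect_equal(sum(r$Sd), want_sd, tolerance = 1e-12)
  # sites: average over the two sequences, N + S = 3 * codons
  expect_equal(r$N_sites + r$S_sites, 3 * r$n_codons)
})

test_that("summed synonymous counts track the simulator truth at low divergence", {
  tree <- timema_tree()
  # rescale so the mean branch length is about 0.01 substitutions/site
  tree$phylo$edge.length <- tree$phylo$edge.length /
    mean(tree$phylo$edge.length) * 0.01
  cfg <- sim_config(
    tree = tree, n_genes = 60, codons_per_gene = 100, seed = 19,
    gene_bias_sd = 0, utr_length = 0
  )
  true_sd <- 0
  est_sd <- 0
  for (g in sprintf("g%04d", 1:60)) {
    sim <- simulate_gene(cfg, g)
    true_sd <- true_sd + sum(sim$truth$synonymous)
    r <- branch_dnds(sim$alignment, tree)
    est_sd <- est_sd + sum(r$Sd)
  }
  expect_gt(true_sd, 200)
  expect_lt(abs(est_sd - true_sd) / true_sd, 0.05)
})

test_that("ortholog filtering reports drop reasons", {
  mk_rate <- function(gene, Nd, Sd) {
    tibble::tibble(
      gene = gene, branch = "b1", terminal = TRUE, mode = "sexual",
      pair_id = 1L, n_codons = 100, N_sites = 230, S_sites = 70,
      Nd = Nd, Sd = Sd, pn = Nd / 230, ps = Sd / 70,
      dN = Nd / 230, dS = Sd / 70,
      omega = ifelse(Sd > 0, (Nd / 230) / (Sd / 70), NA_real_),
      saturated = FALSE, n_excluded = 0L
    )
  }
  rates <- dplyr::bind_rows(
    mk_rate("inv", 0, 0),
    mk_rate("nosyn", 3, 0),
    mk_rate("high", 30, 2),
    mk_rate("ok", 2, 6)
  )
  out <- filter_ortholog_set(rates)
  expect_equal(out$reason[out$gene == "inv"], "no_variation")
  expect_equal(out$reason[out$gene == "nosyn"], "no_synonymous")
  expect_equal(out$reason[out$gene == "high"], "omega_ge_1")
  expect_true(out$retained[out$gene == "ok"])
})

test_that("three-ratio summary recovers symmetric simulations and flags gaps", {
  cfg <- sim_config(
    n_genes = 60, codons_per_gene = 80, seed = 55,
    omega_sexual = 0.2, omega_asexual = 0.2, omega_internal = 0.2,
    gbgc_sexual = 0, gbgc_asexual = 0, gbgc_internal = 0,
    gene_bias_sd = 0, utr_length = 0
  )
  rates <- dplyr::bind_rows(lapply(sprintf("g%04d", 1:60), function(g) {
    sim <- simulate_gene(cfg, g)
    branch_dnds(sim$alignment, cfg$tree)
  }))
  tr <- three_ratio_summary(rates, cfg$tree)
  expect_setequal(
    tr$class, c("asexual_terminal", "sexual_terminal", "internal")
  )
  # equal omega everywhere: class estimates agree within sampling error
  expect_lt(
    max(tr$omega) / min(tr$omega), 1.5
  )
  # class order is invariant to gene concatenation order
  tr_rev <- three_ratio_summary(rates[rev(seq_len(nrow(rates))), ], cfg$tree)
  expect_equal(tr$omega, tr_rev$omega)
  # missing class errors
  expect_error(
    three_ratio_summary(rates[rates$mode != "asexual", ], cfg$tree),
    class = "asexdiv_input"
  )
})
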