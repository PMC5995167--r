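.asexdiv_cache <- new.env(parent = emptyenv())

# Cached single-nucleotide neighbour lookup for a genetic code: 64 x 64
# matrices (indexed by codon position in CODONS) giving changed position,
# exchanged bases, synonymy and W/S class for single-step codon pairs.
neighbor_lookup <- function(code = genetic_code()) {
  key <- rlang::hash(code)
  hit <- .asexdiv_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  nb <- codon_neighbors(code)
  fi <- match(nb$from, CODONS)
  ti <- match(nb$to, CODONS)
  mk <- function(init) matrix(init, 64L, 64L, dimnames = list(CODONS, CODONS))
  pos <- mk(NA_integer_)
  syn <- mk(NA)
  cls <- mk(NA_character_)
  idx <- cbind(fi, ti)
  pos[idx] <- nb$pos
  syn[idx] <- nb$synonymous
  cls[idx] <- nb$class
  out <- list(nb = nb, pos = pos, syn = syn, cls = cls)
  assign(key, out, envir = .asexdiv_cache)
  out
}

# Substitution move table for the codon simulator. Per-change rate:
#   base_rate * kappa^[transition] * omega^[nonsynonymous]
#             * (1+b)^[synonymous W->S] * (1+b)^-[synonymous S->W]
# with base_rate = 1 / (2 + kappa) so that a neutral site accumulates one
# expected substitution per unit branch length; changes into stop codons are
# forbidden. The unbiased baseline is symmetric, so with b = 0 a 50% GC
# composition is stationary and gBGC is the only compositional force.
move_table <- function(kappa, omega, b, code = genetic_code()) {
  nb <- neighbor_lookup(code)$nb
  nb <- nb[!nb$to_stop, , drop = FALSE]
  base_rate <- 1 / (2 + kappa)
  rate <- base_rate *
    ifelse(nb$transition, kappa, 1) *
    ifelse(nb$synonymous, 1, omega) *
    ifelse(nb$synonymous & nb$class == "ws", 1 + b, 1) *
    ifelse(nb$synonymous & nb$class == "sw", 1 / (1 + b), 1)
  fi <- match(nb$from, CODONS)
  ti <- match(nb$to, CODONS)
  moves <- vector("list", 64L)
  tot <- rep(NA_real_, 64L)
  for (i in unique(fi)) {
    sel <- fi == i
    moves[[i]] <- list(to = ti[sel], rate = rate[sel])
    tot[i] <- sum(rate[sel])
  }
  list(moves = moves, tot = tot)
}

#' Simulation configuration
#'
#' Bundles the annotated tree with all parameters of the generative model:
#' branch-specific selection efficacy (omega), GC-biased gene conversion
#' intensity (`b`, a multiplicative boost of synonymous weak-to-strong rates
#' and divisor of strong-to-weak rates), and reproductive-mode-specific
#' polymorphism (segregating-site density, fraction nonsynonymous, pooled
#' read depth and base quality). Defaults encode the study conditions the
#' pipeline is meant to detect: asexual terminal branches have slightly
#' relaxed purifying selection (higher omega), arrested gBGC (`b = 0`),
#' markedly fewer segregating sites and a larger nonsynonymous fraction
#' among them than sexual branches.
#'
#' @param tree An [annotated_tree()]; defaults to [timema_tree()].
#' @param n_genes Number of genes to simulate.
#' @param codons_per_gene Codons per gene.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_sexual,omega_asexual,omega_internal dN/dS on sexual terminal,
#'   asexual terminal and internal branches.
#' @param gbgc_sexual,gbgc_asexual,gbgc_internal gBGC intensity `b >= 0` per
#'   branch class.
#' @param omega_by_branch,gbgc_by_branch Optional named vectors (names are
#'   branch labels from [branch_table()]) overriding the class defaults.
#' @param gene_bias_sd Standard deviation (log scale) of a per-gene
#'   lognormal multiplier on `b`, mimicking gene-to-gene variation in
#'   recombination rate; the same multiplier applies to the gene's UTR, which
#'   is what creates a positive GC_UTR--GC3 correlation across genes.
#' @param root_gc3 Target GC3 of the root sequence, in (0, 1).
#' @param theta_sexual,theta_asexual Expected segregating sites per kb in
#'   pooled population data, by reproductive mode.
#' @param frac_nonsyn_sexual,frac_nonsyn_asexual Fraction of segregating
#'   sites that are nonsynonymous, by mode.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth
#'   model (mean and size).
#' @param phred_mean,phred_sd Gaussian model for per-site mean base quality.
#' @param noise_per_kb Density of sub-threshold noise sites emitted alongside
#'   true variants to exercise the SNP filters.
#' @param utr_length Length (nt) of the simulated untranslated region per
#'   gene; `0` disables UTR simulation.
#' @param seed Master seed; all stages draw from substreams keyed by
#'   `(seed, gene, stage)` so output is fully determined by the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree = timema_tree(),
                       n_genes = 200L,
                       codons_per_gene = 100L,
                       kappa = 2,
                       omega_sexual = 0.15,
                       omega_asexual = 0.18,
                       omega_internal = 0.15,
                       gbgc_sexual = 0.3,
                       gbgc_asexual = 0,
                       gbgc_internal = 0.3,
                       omega_by_branch = NULL,
                       gbgc_by_branch = NULL,
                       gene_bias_sd = 0.5,
                       root_gc3 = 0.5,
                       theta_sexual = 2.0,
                       theta_asexual = 0.25,
                       frac_nonsyn_sexual = 0.3,
                       frac_nonsyn_asexual = 0.5,
                       coverage_mean = 50,
                       coverage_dispersion = 10,
                       phred_mean = 35,
                       phred_sd = 3,
                       noise_per_kb = 2,
                       utr_length = 150L,
                       seed = 1L) {
  if (!inherits(tree, "annotated_tree")) {
    abort("`tree` must be an annotated_tree", class = "asexdiv_config")
  }
  if (!(root_gc3 > 0 && root_gc3 < 1)) {
    abort("`root_gc3` must lie strictly inside (0, 1)", class = "asexdiv_config")
  }
  nums <- c(
    kappa = kappa, omega_sexual = omega_sexual, omega_asexual = omega_asexual,
    omega_internal = omega_internal, gbgc_sexual = gbgc_sexual,
    gbgc_asexual = gbgc_asexual, gbgc_internal = gbgc_internal,
    theta_sexual = theta_sexual, theta_asexual = theta_asexual,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion
  )
  if (any(!is.finite(nums)) || any(nums < 0) || kappa <= 0) {
    abort("rates must be finite and non-negative (kappa > 0)", class = "asexdiv_config")
  }
  if (any(c(frac_nonsyn_sexual, frac_nonsyn_asexual) < 0) ||
    any(c(frac_nonsyn_sexual, frac_nonsyn_asexual) > 1)) {
    abort("nonsynonymous fractions must lie in [0, 1]", class = "asexdiv_config")
  }
  br <- branch_table(tree)
  omega_cls <- c(
    sexual = omega_sexual, asexual = omega_asexual, internal = omega_internal
  )
  b_cls <- c(
    sexual = gbgc_sexual, asexual = gbgc_asexual, internal = gbgc_internal
  )
  br$omega <- unname(omega_cls[br$mode])
  br$b <- unname(b_cls[br$mode])
  if (!is.null(omega_by_branch)) {
    hit <- match(br$branch, names(omega_by_branch))
    br$omega <- ifelse(is.na(hit), br$omega, omega_by_branch[hit])
  }
  if (!is.null(gbgc_by_branch)) {
    hit <- match(br$branch, names(gbgc_by_branch))
    br$b <- ifelse(is.na(hit), br$b, gbgc_by_branch[hit])
  }
  if (any(br$omega < 0) || any(br$b < 0) || any(!is.finite(br$omega + br$b))) {
    abort("branch omega and b must be finite and non-negative", class = "asexdiv_config")
  }
  structure(
    list(
      tree = tree, branches = br,
      n_genes = as.integer(n_genes), codons_per_gene = as.integer(codons_per_gene),
      kappa = kappa, gene_bias_sd = gene_bias_sd, root_gc3 = root_gc3,
      theta_by_mode = c(sexual = theta_sexual, asexual = theta_asexual),
      frac_nonsyn_by_mode = c(
        sexual = frac_nonsyn_sexual, asexual = frac_nonsyn_asexual
      ),
      coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
      phred_mean = phred_mean, phred_sd = phred_sd,
      noise_per_kb = noise_per_kb, utr_length = as.integer(utr_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw n_codons sense codons whose expected GC3 equals root_gc3. The third
# base is drawn first (strong with probability root_gc3, uniform within its
# class); first/second positions are uniform and are resampled for the rare
# draws that would form a stop, which leaves the third-position class
# distribution untouched.
sim_root_codons <- function(n_codons, root_gc3, code = genetic_code()) {
  strong <- stats::runif(n_codons) < root_gc3
  third <- ifelse(strong,
    sample(c("G", "C"), n_codons, replace = TRUE),
    sample(c("A", "T"), n_codons, replace = TRUE)
  )
  p1 <- sample(BASES, n_codons, replace = TRUE)
  p2 <- sample(BASES, n_codons, replace = TRUE)
  codons <- paste0(p1, p2, third)
  bad <- code[codons] == "*"
  while (any(bad)) {
    k <- sum(bad)
    codons[bad] <- paste0(
      sample(BASES, k, replace = TRUE), sample(BASES, k, replace = TRUE),
      third[bad]
    )
    bad <- code[codons] == "*"
  }
  codons
}

#' Simulate a root coding sequence
#'
#' @param config A [sim_config()].
#' @param gene_id Optional gene id keying the RNG substream.
#' @param code Genetic code.
#' @return A coding sequence string of `config$codons_per_gene` codons with
#'   expected GC3 equal to `config$root_gc3` and no stop codons.
#' @export
simulate_root <- function(config, gene_id = "root", code = genetic_code()) {
  with_substream(config$seed, gene_id, "root",
    expr = paste0(
      sim_root_codons(config$codons_per_gene, config$root_gc3, code),
      collapse = ""
    )
  )
}

# Gillespie walk over codon states; returns final states plus the event log.
evolve_codons <- function(idx, t_len, mt) {
  L <- length(idx)
  tot <- mt$tot[idx]
  ev_site <- integer(0)
  ev_from <- integer(0)
  ev_to <- integer(0)
  ev_time <- numeric(0)
  elapsed <- 0
  R <- sum(tot)
  repeat {
    if (R <= 0) break
    elapsed <- elapsed + stats::rexp(1L, R)
    if (elapsed > t_len) break
    site <- sample.int(L, 1L, prob = tot)
    mv <- mt$moves[[idx[site]]]
    k <- if (length(mv$rate) == 1L) 1L else sample.int(length(mv$rate), 1L, prob = mv$rate)
    ev_site <- c(ev_site, site)
    ev_from <- c(ev_from, idx[site])
    ev_to <- c(ev_to, mv$to[k])
    ev_time <- c(ev_time, elapsed)
    R <- R - tot[site]
    idx[site] <- mv$to[k]
    tot[site] <- mt$tot[idx[site]]
    R <- R + tot[site]
  }
  list(idx = idx, site = ev_site, from = ev_from, to = ev_to, time = ev_time)
}

#' Evolve a coding sequence along one branch
#'
#' Continuous-time (Gillespie) codon substitution. Single-nucleotide codon
#' changes occur at rate `base_rate * kappa^[ts] * omega^[nonsyn]`, with
#' synonymous weak-to-strong changes boosted by `(1 + b)` and synonymous
#' strong-to-weak changes slowed by the same factor; stop codons are
#' unreachable. `base_rate` is normalised so a neutral site expects one
#' substitution per unit branch length.
#'
#' @param seq In-frame coding sequence (string, no gaps).
#' @param branch_length Branch length (expected neutral substitutions per
#'   nucleotide site).
#' @param omega,kappa,gbgc_b Process parameters.
#' @param code Genetic code.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return The descendant sequence string, with the substitution log
#'   attached as attribute `"events"` (a tibble).
#' @export
evolve_branch <- function(seq, branch_length, omega, kappa = 2, gbgc_b = 0,
                          code = genetic_code(), seed = NULL) {
  idx <- match(split_codons(seq), CODONS)
  if (anyNA(idx) || any(code[idx] == "*")) {
    abort("sequence must consist of sense codons", class = "asexdiv_input")
  }
  mt <- move_table(kappa, omega, gbgc_b, code)
  run <- function() evolve_codons(idx, branch_length, mt)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- paste0(CODONS[res$idx], collapse = "")
  attr(out, "events") <- event_log(res, code)
  out
}

event_log <- function(res, code = genetic_code()) {
  lk <- neighbor_lookup(code)
  ij <- cbind(res$from, res$to)
  pos <- lk$pos[ij]
  from_codon <- CODONS[res$from]
  to_codon <- CODONS[res$to]
  tibble::new_tibble(list(
    site = res$site, pos = pos,
    from_codon = from_codon, to_codon = to_codon,
    from_base = substr(from_codon, pos, pos),
    to_base = substr(to_codon, pos, pos),
    synonymous = as.logical(lk$syn[ij]), class = as.character(lk$cls[ij]),
    time = res$time
  ), nrow = length(pos))
}

#' Simulate one gene along the annotated tree
#'
#' Applies [evolve_branch()] pre-order from a simulated root, with
#' branch-specific omega and gBGC intensity from the configuration (times
#' the gene's recombination-rate multiplier). No indels are simulated, so
#' the tip sequences are already aligned.
#'
#' @param config A [sim_config()].
#' @param gene_id Gene identifier (keys the RNG substream).
#' @param code Genetic code.
#' @return A list with elements `alignment` (a [codon_alignment()] over the
#'   tips), `truth` (tibble of true substitutions with columns `gene`,
#'   `branch`, `site`, `pos`, `from_codon`, `to_codon`, `from_base`,
#'   `to_base`, `synonymous`, `class`, `time`) and `bias` (the gene's gBGC
#'   multiplier).
#' @export
simulate_gene <- function(config, gene_id, code = genetic_code()) {
  phylo <- config$tree$phylo
  if (length(phylo$tip.label) < 2L) {
    abort("tree needs at least two tips", class = "asexdiv_config")
  }
  bias <- if (config$gene_bias_sd > 0) {
    with_substream(config$seed, gene_id, "bias",
      expr = stats::rlnorm(1L, 0, config$gene_bias_sd)
    )
  } else {
    1
  }
  br <- config$branches
  with_substream(config$seed, gene_id, "evolve", expr = {
    root_idx <- match(
      sim_root_codons(config$codons_per_gene, config$root_gc3, code), CODONS
    )
    ntip <- length(phylo$tip.label)
    root_node <- ntip + 1L
    lab <- node_labels(phylo)
    seqs <- vector("list", ntip + phylo$Nnode)
    seqs[[root_node]] <- root_idx
    mts <- list()
    logs <- vector("list", nrow(br))
    ord <- order(br$edge_id) # cladewise edge order = pre-order traversal
    for (e in ord) {
      key <- paste(br$omega[e], br$b[e] * bias)
      if (is.null(mts[[key]])) {
        mts[[key]] <- move_table(config$kappa, br$omega[e], br$b[e] * bias, code)
      }
      res <- evolve_codons(seqs[[br$parent[e]]], br$length[e], mts[[key]])
      seqs[[br$child[e]]] <- res$idx
      lg <- event_log(res, code)
      if (nrow(lg) > 0L) {
        lg <- dplyr::mutate(lg, gene = gene_id, branch = br$branch[e], .before = 1L)
      }
      logs[[e]] <- lg
    }
    tips <- stats::setNames(
      vapply(seq_len(ntip), function(i) paste0(CODONS[seqs[[i]]], collapse = ""), ""),
      phylo$tip.label
    )
    list(
      alignment = codon_alignment(gene_id, tips),
      truth = dplyr::bind_rows(logs[vapply(logs, nrow, 0L) > 0]),
      bias = bias
    )
  })
}

# Neutral nucleotide-level evolution for a UTR, with the gene's gBGC bias
# applied to every change (the region is untranslated).
simulate_utr <- function(config, gene_id, bias, code = genetic_code()) {
  if (config$utr_length <= 0L) {
    return(NULL)
  }
  phylo <- config$tree$phylo
  br <- config$branches
  base_rate <- 1 / (2 + config$kappa)
  grid <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  ts_mat <- matrix(is_transition(grid$from, grid$to), 4, 4, dimnames = list(BASES, BASES))
  cls_mat <- matrix(change_class(grid$from, grid$to), 4, 4, dimnames = list(BASES, BASES))
  rate_cache <- list()
  rate_mat <- function(b) {
    key <- format(b, digits = 12)
    hit <- rate_cache[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    m <- base_rate * ifelse(ts_mat, config$kappa, 1) *
      ifelse(cls_mat == "ws", 1 + b, ifelse(cls_mat == "sw", 1 / (1 + b), 1))
    diag(m) <- 0
    rate_cache[[key]] <<- m
    m
  }
  with_substream(config$seed, gene_id, "utr", expr = {
    L <- config$utr_length
    root <- sample.int(4L, L, replace = TRUE)
    ntip <- length(phylo$tip.label)
    seqs <- vector("list", ntip + phylo$Nnode)
    seqs[[ntip + 1L]] <- root
    for (e in order(br$edge_id)) {
      Q <- rate_mat(br$b[e] * bias)
      tot <- rowSums(Q)
      s <- seqs[[br$parent[e]]]
      elapsed <- 0
      repeat {
        R <- sum(tot[s])
        elapsed <- elapsed + stats::rexp(1L, R)
        if (elapsed > br$length[e]) break
        site <- sample.int(L, 1L, prob = tot[s])
        s[site] <- sample.int(4L, 1L, prob = Q[s[site], ])
      }
      seqs[[br$child[e]]] <- s
    }
    tibble(
      gene = gene_id,
      species = phylo$tip.label,
      utr = vapply(seq_len(ntip), function(i) paste0(BASES[seqs[[i]]], collapse = ""), "")
    )
  })
}

#' Simulate a pooled-population pileup for one tip sequence
#'
#' Places segregating sites along the open reading frame at the density
#' configured for the tip's reproductive mode, assigns each an alternate
#' allele (nonsynonymous with the mode's configured probability, otherwise
#' synonymous where the codon permits), a true minor-allele frequency drawn
#' uniformly on `[0.1, 0.5]`, a negative-binomial read depth, binomial
#' allele counts and a Gaussian mean base quality. Additional sub-threshold
#' noise sites (low coverage, low frequency, or low quality) are emitted to
#' exercise the SNP filters.
#'
#' @param seq The tip coding sequence (string).
#' @param mode `"sexual"` or `"asexual"`.
#' @param config A [sim_config()].
#' @param gene_id Gene id used for bookkeeping and the RNG substream.
#' @param species Species label used for the RNG substream.
#' @param code Genetic code.
#' @return A list with `sites` (tibble: `gene`, `pos` 0-based, `ref`, `A`,
#'   `C`, `G`, `T`, `mean_phred`) and `truth` (tibble of the true variant
#'   sites with `pos`, `alt`, `effect`, `maf`).
#' @export
simulate_pileup <- function(seq, mode, config, gene_id = "g1",
                            species = mode, code = genetic_code()) {
  with_substream(config$seed, gene_id, "pileup", species, expr = {
    bases <- split_bases(seq)
    L <- length(bases)
    codons <- split_codons(seq)
    nb <- neighbor_lookup(code)$nb
    theta <- config$theta_by_mode[[mode]]
    frac_ns <- config$frac_nonsyn_by_mode[[mode]]
    n_var <- stats::rpois(1L, theta * L / 1000)
    n_var <- min(n_var, L)
    # sites offering a synonymous (resp. nonsynonymous) alternate allele;
    # the variant's effect is drawn first and its site sampled conditional
    # on that effect, so the realised nonsynonymous fraction matches the
    # configured one
    site_info <- dplyr::mutate(nb[!nb$to_stop, ],
      key = paste(.data$from, .data$pos)
    )
    by_key <- split(seq_len(nrow(site_info)), site_info$key)
    pos_key <- paste(codons[((seq_len(L)) - 1L) %/% 3L + 1L], (seq_len(L) - 1L) %% 3L + 1L)
    has_eff <- function(syn) {
      keys <- unique(site_info$key[site_info$synonymous == syn])
      which(pos_key %in% keys)
    }
    syn_sites <- has_eff(TRUE)
    ns_sites <- has_eff(FALSE)
    want_ns <- stats::runif(n_var) < frac_ns
    var_pos <- integer(0)
    eff_sel <- logical(0)
    avail_syn <- syn_sites
    avail_ns <- ns_sites
    for (k in seq_len(n_var)) {
      pool <- if (want_ns[k]) avail_ns else avail_syn
      if (length(pool) == 0L) pool <- if (want_ns[k]) avail_syn else avail_ns
      if (length(pool) == 0L) break
      p <- pool[sample.int(length(pool), 1L)]
      var_pos <- c(var_pos, p)
      eff_sel <- c(eff_sel, want_ns[k])
      avail_syn <- setdiff(avail_syn, p)
      avail_ns <- setdiff(avail_ns, p)
    }
    n_var <- length(var_pos)
    ord0 <- order(var_pos)
    var_pos <- var_pos[ord0]
    eff_sel <- eff_sel[ord0]

    alt <- character(n_var)
    effect <- character(n_var)
    for (k in seq_len(n_var)) {
      p <- var_pos[k]
      ci <- (p - 1L) %/% 3L + 1L
      cp <- (p - 1L) %% 3L + 1L
      opts <- site_info[by_key[[paste(codons[ci], cp)]], , drop = FALSE]
      pick <- opts[opts$synonymous != eff_sel[k], , drop = FALSE]
      if (nrow(pick) == 0L) pick <- opts
      j <- sample.int(nrow(pick), 1L)
      alt[k] <- pick$to_base[j]
      effect[k] <- if (pick$synonymous[j]) "synonymous" else "nonsynonymous"
    }
    maf <- stats::runif(n_var, 0.1, 0.5)

    depth_draw <- function(n) {
      pmax(1L, stats::rnbinom(n,
        mu = config$coverage_mean,
        size = config$coverage_dispersion
      ))
    }
    phred_draw <- function(n) {
      pmax(2, stats::rnorm(n, config$phred_mean, config$phred_sd))
    }
    depth <- depth_draw(n_var)
    alt_n <- stats::rbinom(n_var, depth, maf)

    # Noise sites: each deliberately fails exactly one of the three filters.
    n_noise <- stats::rpois(1L, config$noise_per_kb * L / 1000)
    free <- setdiff(seq_len(L), var_pos)
    n_noise <- min(n_noise, length(free))
    noise_pos <- if (n_noise > 0L) sort(sample(free, n_noise)) else integer(0)
    fail <- sample(c("cov", "maf", "phred"), n_noise, replace = TRUE)
    nz_depth <- ifelse(fail == "cov", sample(5:19, n_noise, replace = TRUE), depth_draw(n_noise))
    nz_frac <- ifelse(fail == "maf", stats::runif(n_noise, 0.01, 0.07),
      stats::runif(n_noise, 0.1, 0.5)
    )
    nz_phred <- ifelse(fail == "phred", stats::runif(n_noise, 10, 19.5), phred_draw(n_noise))
    nz_alt <- stats::rbinom(n_noise, nz_depth, nz_frac)
    nz_base <- vapply(noise_pos, function(p) sample(setdiff(BASES, bases[p]), 1L), "")

    all_pos <- c(var_pos, noise_pos)
    all_ref <- bases[all_pos]
    all_alt_base <- c(alt, nz_base)
    all_depth <- c(depth, nz_depth)
    all_alt_n <- pmin(c(alt_n, nz_alt), all_depth)
    all_phred <- c(phred_draw(n_var), nz_phred)

    counts <- matrix(0L, length(all_pos), 4L, dimnames = list(NULL, BASES))
    for (k in seq_along(all_pos)) {
      counts[k, all_ref[k]] <- all_depth[k] - all_alt_n[k]
      counts[k, all_alt_base[k]] <- counts[k, all_alt_base[k]] + all_alt_n[k]
    }
    ord <- order(all_pos)
    sites <- tibble(
      gene = gene_id,
      pos = all_pos[ord] - 1L,
      ref = all_ref[ord],
      A = counts[ord, "A"], C = counts[ord, "C"],
      G = counts[ord, "G"], T = counts[ord, "T"],
      mean_phred = round(all_phred[ord], 2)
    )
    truth <- tibble(
      gene = gene_id, pos = var_pos - 1L, alt = alt, effect = effect, maf = maf
    )
    list(sites = sites, truth = truth)
  })
}

#' Simulate a full comparative study
#'
#' Runs [simulate_gene()], [simulate_pileup()] (for every tip) and the UTR
#' simulator for `n_genes` genes, producing everything the downstream
#' pipeline consumes plus the ground-truth substitution and variant logs.
#'
#' @param config A [sim_config()].
#' @param code Genetic code.
#' @return An object of class `asexdiv_sim`: a list with `config`, `tree`,
#'   `alignments` (named list of [codon_alignment()]), `truth` (substitution
#'   log tibble), `pileups` (tibble with `species`, `gene`, `pos`, `ref`,
#'   base counts, `mean_phred`), `snp_truth`, and `utrs` (tibble or `NULL`).
#' @export
simulate_study <- function(config, code = genetic_code()) {
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  meta <- config$tree$meta
  alignments <- vector("list", length(gene_ids))
  truths <- vector("list", length(gene_ids))
  utrs <- vector("list", length(gene_ids))
  pileups <- vector("list", length(gene_ids))
  snp_truths <- vector("list", length(gene_ids))
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    sim <- simulate_gene(config, g, code)
    alignments[[i]] <- sim$alignment
    truths[[i]] <- sim$truth
    utrs[[i]] <- simulate_utr(config, g, sim$bias, code)
    per_sp <- lapply(meta$tip, function(sp) {
      mode <- meta$mode[meta$tip == sp]
      pu <- simulate_pileup(sim$alignment$seqs[[sp]], mode, config,
        gene_id = g, species = sp, code = code
      )
      list(
        sites = dplyr::mutate(pu$sites, species = sp, .before = 1L),
        truth = dplyr::mutate(pu$truth, species = sp, .before = 1L)
      )
    })
    pileups[[i]] <- dplyr::bind_rows(lapply(per_sp, `[[`, "sites"))
    snp_truths[[i]] <- dplyr::bind_rows(lapply(per_sp, `[[`, "truth"))
  }
  names(alignments) <- gene_ids
  structure(
    list(
      config = config, tree = config$tree,
      alignments = alignments,
      truth = dplyr::bind_rows(truths),
      pileups = dplyr::bind_rows(pileups),
      snp_truth = dplyr::bind_rows(snp_truths),
      utrs = if (config$utr_length > 0L) dplyr::bind_rows(utrs) else NULL
    ),
    class = "asexdiv_sim"
  )
}

#' @export
print.asexdiv_sim <- function(x, ...) {
  cat(sprintf(
    "<asexdiv_sim> %d genes x %d codons, %d tips; %d true substitutions, %d true variants\n",
    length(x$alignments), x$config$codons_per_gene,
    length(x$tree$phylo$tip.label), nrow(x$truth), nrow(x$snp_truth)
  ))
  invisible(x)
}
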