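# Direct simulator for the two-state (weak/strong) chain used by the
# equilibrium-GC3 model: draws third-position states down the tree from the
# model itself, bypassing the codon simulator. Used for stationary-recovery
# and likelihood-ratio calibration tests.
simulate_two_state <- function(tree, theta, n_columns, rho = 1, seed = 1) {
  phylo <- tree$phylo
  withr::with_seed(seed, {
    ntip <- length(phylo$tip.label)
    states <- vector("list", ntip + phylo$Nnode)
    states[[ntip + 1L]] <- as.integer(stats::runif(n_columns) < theta)
    for (e in seq_len(nrow(phylo$edge))) {
      par <- phylo$edge[e, 1L]
      ch <- phylo$edge[e, 2L]
      P <- asexdiv:::p_two_state(theta, rho * phylo$edge.length[e])
      s <- states[[par]]
      # row 1 = W(0), row 2 = S(1); draw next state per column
      p_s <- ifelse(s == 1L, P[2L, 2L], P[1L, 2L])
      states[[ch]] <- as.integer(stats::runif(n_columns) < p_s)
    }
    tips <- states[seq_len(ntip)]
    names(tips) <- phylo$tip.label
    tips
  })
}

# Wrap tip W/S states into a codon alignment whose third positions carry the
# states (first two positions held fixed at "GG", so every codon is sense).
two_state_alignment <- function(tips, gene_id = "ts") {
  seqs <- vapply(tips, function(s) {
    paste0("GG", ifelse(s == 1L, "C", "T"), collapse = "")
  }, "")
  codon_alignment(gene_id, seqs)
}
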