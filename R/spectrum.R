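#' Classify synonymous substitutions into W->S, S->W and GC-conservative
#'
#' Maps the synonymous substitutions implied by an ancestral reconstruction
#' onto each branch and classifies them by base strength: weak-to-strong
#' (A/T -> G/C), strong-to-weak (G/C -> A/T) and GC-conservative (A <-> T,
#' G <-> C). Under arrested gBGC, asexual branches are expected to show a
#' higher strong-to-weak and lower weak-to-strong proportion than their
#' sexual sisters.
#'
#' Codon pairs differing at one position contribute their category directly.
#' Pairs differing at several positions are resolved by enumerating every
#' ordering of the changed positions through sense codons: when all such
#' orderings keep every step synonymous, each step's category is counted
#' with weight `1/n_orderings`; otherwise the codon is excluded
#' (conservative) and logged.
#'
#' @param recs One [reconstruct_ancestors()] result or a list of them (one
#'   per gene); counts are summed across genes.
#' @param code Genetic code.
#' @param terminal_only Restrict to terminal branches (default), where the
#'   reproductive mode is known.
#' @return A tibble of class `substitution_spectrum` with one row per
#'   branch: `branch`, `mode`, `pair_id`, `ws`, `sw`, `cons`, `total`,
#'   `prop_ws`, `prop_sw`, `prop_cons`, `n_excluded`.
#' @export
classify_synonymous_substitutions <- function(recs, code = genetic_code(),
                                              terminal_only = TRUE) {
  if (inherits(recs, "ancestral_rec")) recs <- list(recs)
  per_gene <- purrr::map(recs, function(rec) {
    ed <- edge_sequences(rec)
    if (terminal_only) ed <- ed[ed$terminal, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(ed)), function(i) {
      cnt <- spectrum_branch(ed$parent_seq[i], ed$child_seq[i], code)
      tibble(
        branch = ed$branch[i], mode = ed$mode[i], pair_id = ed$pair_id[i],
        ws = cnt[["ws"]], sw = cnt[["sw"]], cons = cnt[["cons"]],
        n_excluded = cnt[["excluded"]]
      )
    })
  })
  out <- dplyr::bind_rows(per_gene)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$branch, .data$mode, .data$pair_id),
    dplyr::across(c("ws", "sw", "cons", "n_excluded"), sum),
    .groups = "drop"
  )
  out$total <- out$ws + out$sw + out$cons
  out$prop_ws <- ifelse(out$total > 0, out$ws / out$total, NA_real_)
  out$prop_sw <- ifelse(out$total > 0, out$sw / out$total, NA_real_)
  out$prop_cons <- ifelse(out$total > 0, out$cons / out$total, NA_real_)
  class(out) <- c("substitution_spectrum", class(out))
  out
}

# Category counts for one branch (parent vs child sequence).
spectrum_branch <- function(parent_seq, child_seq, code = genetic_code()) {
  p <- split_codons(parent_seq)
  c_ <- split_codons(child_seq)
  ok <- p %in% sense_codons(code) & c_ %in% sense_codons(code)
  diff <- ok & p != c_
  out <- c(ws = 0, sw = 0, cons = 0, excluded = 0)
  for (i in which(diff)) {
    cp <- codon_paths(p[i], c_[i], code)
    if (cp$n_valid == 0L) {
      out[["excluded"]] <- out[["excluded"]] + 1
      next
    }
    all_syn <- vapply(cp$paths, function(path) {
      all(vapply(path, `[[`, TRUE, "synonymous"))
    }, TRUE)
    if (!all(all_syn)) {
      if (length(cp$paths[[1L]]) > 1L) {
        out[["excluded"]] <- out[["excluded"]] + 1
      }
      # single-position nonsynonymous changes simply aren't synonymous
      # substitutions; nothing to count or exclude
      next
    }
    w <- 1 / cp$n_valid
    for (path in cp$paths) {
      for (step in path) {
        out[[step$class]] <- out[[step$class]] + w
      }
    }
  }
  out
}
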