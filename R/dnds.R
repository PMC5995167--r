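jc_correct <- function(p) {
  ifelse(p <= 0, 0, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.eps)))
}

#' Per-branch dN/dS by ancestral reconstruction and counting
#'
#' A counting analogue of a "free" branch model: every branch of the tree
#' gets its own omega. For each branch, the parent and child sequences from
#' the parsimony reconstruction are compared codon by codon;
#' synonymous/nonsynonymous differences are counted with multi-position
#' codons averaged over all stop-free mutational paths (Nei--Gojobori), site
#' counts are averaged over the two sequences, and the per-site proportions
#' are Jukes--Cantor corrected into `dN` and `dS`. `omega = dN/dS` is `NA`
#' where `dS = 0`, and branches with synonymous proportions at or beyond the
#' correction's domain (`ps >= 3/4`) are flagged as saturated and excluded.
#'
#' @param alignment A [codon_alignment()].
#' @param tree An [annotated_tree()].
#' @param ancestors Optional [reconstruct_ancestors()] result (computed if
#'   missing).
#' @param code Genetic code.
#' @return A tibble of class `branch_rates`: one row per branch with
#'   `gene`, `branch`, `terminal`, `mode`, `pair_id`, `n_codons`, `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pn`, `ps`, `dN`, `dS`, `omega`, `saturated`,
#'   `n_excluded` (codon pairs with no stop-free path).
#' @export
branch_dnds <- function(alignment, tree, ancestors = NULL, code = genetic_code()) {
  rec <- ancestors %||% reconstruct_ancestors(alignment, tree)
  ed <- edge_sequences(rec)
  sense <- sense_codons(code)
  out <- purrr::map_dfr(seq_len(nrow(ed)), function(i) {
    p <- split_codons(ed$parent_seq[i])
    ch <- split_codons(ed$child_seq[i])
    ok <- p %in% sense & ch %in% sense
    p <- p[ok]
    ch <- ch[ok]
    sp <- ng86_sites(paste0(p, collapse = ""), code)
    sc <- ng86_sites(paste0(ch, collapse = ""), code)
    N <- (sp[["N_sites"]] + sc[["N_sites"]]) / 2
    S <- (sp[["S_sites"]] + sc[["S_sites"]]) / 2
    nd <- 0
    sd <- 0
    excl <- 0L
    for (j in which(p != ch)) {
      cnt <- codon_pair_counts(p[j], ch[j], code)
      if (is.null(cnt)) {
        excl <- excl + 1L
        next
      }
      nd <- nd + cnt[["nd"]]
      sd <- sd + cnt[["sd"]]
    }
    pn <- if (N > 0) nd / N else 0
    ps <- if (S > 0) sd / S else 0
    saturated <- ps >= 0.75 || pn >= 0.75
    dN <- if (saturated) NA_real_ else jc_correct(pn)
    dS <- if (saturated) NA_real_ else jc_correct(ps)
    tibble(
      gene = rec$gene_id, branch = ed$branch[i], terminal = ed$terminal[i],
      mode = ed$mode[i], pair_id = ed$pair_id[i],
      n_codons = length(p), N_sites = N, S_sites = S,
      Nd = nd, Sd = sd, pn = pn, ps = ps, dN = dN, dS = dS,
      omega = ifelse(!saturated & !is.na(dS) & dS > 0, dN / dS, NA_real_),
      saturated = saturated, n_excluded = excl
    )
  })
  class(out) <- c("branch_rates", class(out))
  out
}

#' @rdname branch_dnds
#' @param alignments A named list of alignments; results are row-bound.
#' @export
branch_dnds_many <- function(alignments, tree, code = genetic_code()) {
  out <- dplyr::bind_rows(purrr::map(alignments, branch_dnds, tree = tree, code = code))
  class(out) <- c("branch_rates", class(out))
  out
}

#' Filter the ortholog set for purifying-selection contrasts
#'
#' Mirrors the standard pre-filtering for comparisons of purifying-selection
#' efficacy: genes with no substitutions anywhere on the tree carry no
#' signal ("no variation"), and genes whose gene-level omega (from counts
#' pooled across branches) reaches 1, or which have no synonymous
#' substitutions at all, cannot be interpreted as purifying selection.
#'
#' @param rates A `branch_rates` tibble covering all genes.
#' @return A tibble with one row per gene: pooled `Nd`, `Sd`, `dN`, `dS`,
#'   `omega`, a `reason` (`NA` for retained genes, otherwise
#'   `"no_variation"`, `"no_synonymous"` or `"omega_ge_1"`), and `retained`.
#' @export
filter_ortholog_set <- function(rates) {
  pooled <- dplyr::summarise(
    dplyr::group_by(rates, .data$gene),
    Nd = sum(.data$Nd), Sd = sum(.data$Sd),
    N_sites = sum(.data$N_sites), S_sites = sum(.data$S_sites),
    .groups = "drop"
  )
  pooled$dN <- jc_correct(pooled$Nd / pmax(pooled$N_sites, 1e-12))
  pooled$dS <- jc_correct(pooled$Sd / pmax(pooled$S_sites, 1e-12))
  pooled$omega <- ifelse(pooled$dS > 0, pooled$dN / pooled$dS, NA_real_)
  pooled$reason <- dplyr::case_when(
    pooled$Nd + pooled$Sd == 0 ~ "no_variation",
    pooled$Sd == 0 ~ "no_synonymous",
    pooled$omega >= 1 ~ "omega_ge_1",
    TRUE ~ NA_character_
  )
  pooled$retained <- is.na(pooled$reason)
  pooled
}

#' Three-ratio summary of branch rates
#'
#' Pools observed substitution and site counts within three branch classes
#' -- asexual terminal, sexual terminal and internal -- and reports a single
#' dN/dS per class, the counting analogue of a three-ratio branch model.
#' An equal-gene-weight mean of per-branch omega values is reported
#' alongside the count-pooled estimate.
#'
#' @param rates A `branch_rates` tibble.
#' @param tree An [annotated_tree()] (used only to check class coverage).
#' @return A tibble with one row per class: pooled `Nd`, `Sd`, `N_sites`,
#'   `S_sites`, `pn`, `ps`, `dN`, `dS`, `omega` (NA and flagged if the
#'   class has no synonymous substitutions) and `mean_omega`.
#' @export
three_ratio_summary <- function(rates, tree) {
  rates$class <- dplyr::case_when(
    !rates$terminal ~ "internal",
    rates$mode == "asexual" ~ "asexual_terminal",
    TRUE ~ "sexual_terminal"
  )
  need <- c("asexual_terminal", "sexual_terminal", "internal")
  if (!all(need %in% unique(rates$class))) {
    abort("a branch class is empty; need asexual, sexual and internal branches",
      class = "asexdiv_input"
    )
  }
  out <- dplyr::summarise(
    dplyr::group_by(rates, .data$class),
    Nd = sum(.data$Nd), Sd = sum(.data$Sd),
    N_sites = sum(.data$N_sites), S_sites = sum(.data$S_sites),
    mean_omega = mean(.data$omega, na.rm = TRUE),
    .groups = "drop"
  )
  out$pn <- out$Nd / out$N_sites
  out$ps <- out$Sd / out$S_sites
  out$dN <- jc_correct(out$pn)
  out$dS <- jc_correct(out$ps)
  out$omega <- ifelse(out$Sd > 0, out$dN / out$dS, NA_real_)
  if (any(out$Sd == 0)) {
    warn("a branch class has no synonymous substitutions; its omega is NA")
  }
  out[match(need, out$class), ]
}
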