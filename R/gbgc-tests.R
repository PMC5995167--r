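#' Paired per-gene GC3 comparison within species pairs
#'
#' For each sexual--asexual pair, compares per-gene GC3 between the two
#' species with a Wilcoxon signed-rank test (exact ties dropped) and reports
#' the proportion of genes in which the sexual species has the higher GC3
#' (computed over non-tied genes; `NA` when every gene is tied) together
#' with the ratio of among-gene GC3 variances. Ongoing gBGC in the sexual
#' lineage predicts proportions above 0.5 and a higher sexual variance.
#'
#' @param gene_table A tibble with columns `gene`, `species`, `gc3` (one row
#'   per gene x species), e.g. from [run_pipeline()]'s gene table.
#' @param tree An [annotated_tree()].
#' @param strict Abort (classed error `asexdiv_no_test`) when a pair has
#'   fewer than two non-tied genes; when `FALSE`, such pairs get `NA`
#'   results.
#' @return A tibble with one row per pair: `pair_id`, `sexual`, `asexual`,
#'   `n_genes`, `n_ties`, `prop_sex_higher`, `var_ratio`
#'   (sexual / asexual among-gene variance), `wilcoxon_p`.
#' @export
gc3_pair_comparison <- function(gene_table, tree, strict = TRUE) {
  meta <- tree$meta
  purrr::map_dfr(sort(unique(meta$pair_id)), function(pid) {
    sx <- meta$tip[meta$pair_id == pid & meta$mode == "sexual"]
    ax <- meta$tip[meta$pair_id == pid & meta$mode == "asexual"]
    wide <- dplyr::inner_join(
      dplyr::filter(gene_table, .data$species == sx)[, c("gene", "gc3")],
      dplyr::filter(gene_table, .data$species == ax)[, c("gene", "gc3")],
      by = "gene", suffix = c("_sex", "_asex")
    )
    d <- wide$gc3_sex - wide$gc3_asex
    nontied <- d != 0
    prop <- if (sum(nontied) == 0L) NA_real_ else mean(d[nontied] > 0)
    p <- if (sum(nontied) < 2L) {
      if (strict) {
        abort(sprintf("pair %s: fewer than 2 non-tied genes; no test possible", pid),
          class = "asexdiv_no_test"
        )
      }
      NA_real_
    } else {
      suppressWarnings(
        stats::wilcox.test(wide$gc3_sex, wide$gc3_asex, paired = TRUE)$p.value
      )
    }
    tibble(
      pair_id = pid, sexual = sx, asexual = ax,
      n_genes = nrow(wide), n_ties = sum(!nontied),
      prop_sex_higher = prop,
      var_ratio = stats::var(wide$gc3_sex) / stats::var(wide$gc3_asex),
      wilcoxon_p = p
    )
  })
}

#' Correlation between UTR GC content and GC3 across genes
#'
#' A positive Pearson correlation between `gc_utr` and `gc3` across genes,
#' within each species, indicates that third-position composition is shaped
#' by a regional force acting on translated and untranslated sequence alike
#' (gBGC tracking local recombination rate) rather than by translational
#' selection.
#'
#' @param gene_table Tibble with columns `species`, `gene`, `gc3`, `gc_utr`.
#' @param strict Abort (classed `asexdiv_no_test`) on species with fewer
#'   than 3 complete genes or zero variance; otherwise return `NA` rows.
#' @return Tibble with one row per species: `species`, `n_genes`, `r`,
#'   `t`, `df`, `p`.
#' @export
gc_utr_correlation <- function(gene_table, strict = TRUE) {
  purrr::map_dfr(sort(unique(gene_table$species)), function(sp) {
    d <- dplyr::filter(
      gene_table, .data$species == sp,
      !is.na(.data$gc3), !is.na(.data$gc_utr)
    )
    bad <- nrow(d) < 3L || stats::var(d$gc3) == 0 || stats::var(d$gc_utr) == 0
    if (bad) {
      if (strict) {
        abort(sprintf("species %s: need >= 3 genes with variation in both GC measures", sp),
          class = "asexdiv_no_test"
        )
      }
      return(tibble(
        species = sp, n_genes = nrow(d), r = NA_real_, t = NA_real_,
        df = NA_integer_, p = NA_real_
      ))
    }
    ct <- stats::cor.test(d$gc3, d$gc_utr, method = "pearson")
    tibble(
      species = sp, n_genes = nrow(d),
      r = unname(ct$estimate), t = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value
    )
  })
}
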