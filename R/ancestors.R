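# Bit encoding of nucleotide state sets: A=1, C=2, G=4, T=8.
.bit_of <- c(A = 1L, C = 2L, G = 4L, T = 8L)
# lowbit_base[s] = base of the lowest set bit of s (fixed A < C < G < T order)
.lowbit_base <- vapply(1:15, function(s) {
  c("A", "C", "G", "T")[which(bitwAnd(s, c(1L, 2L, 4L, 8L)) > 0L)[1L]]
}, "")

#' Ancestral sequence reconstruction by Fitch parsimony
#'
#' Reconstructs nucleotide sequences at every internal node of the rooted
#' tree by column-wise Fitch parsimony: a post-order pass builds state sets
#' (intersection where non-empty, union otherwise) and a pre-order pass
#' resolves each node to a single state, preferring the parent's state and
#' otherwise the first state in the fixed order A < C < G < T, which makes
#' the reconstruction deterministic. Columns containing a gap or ambiguity
#' code in any tip are excluded from mapping and reported as `-` at internal
#' nodes.
#'
#' @param alignment A [codon_alignment()] covering all tree tips.
#' @param tree An [annotated_tree()].
#' @return An object of class `ancestral_rec`: list with `sequences` (named
#'   character vector over all node labels, tips first), `excluded_columns`
#'   (integer positions skipped), `gene_id`, and `tree`.
#' @export
reconstruct_ancestors <- function(alignment, tree) {
  phylo <- tree$phylo
  tips <- phylo$tip.label
  if (!all(tips %in% alignment$taxa)) {
    abort("alignment must cover all tree tips", class = "asexdiv_input")
  }
  n <- nchar(alignment$seqs[[1L]])
  ntip <- length(tips)
  nnode <- phylo$Nnode
  lab <- node_labels(phylo)

  tipmat <- t(vapply(tips, function(tx) split_bases(alignment$seqs[[tx]]), character(n)))
  excluded <- which(colSums(matrix(!tipmat %in% BASES, nrow = ntip)) > 0L)
  keep <- setdiff(seq_len(n), excluded)

  sets <- matrix(0L, nrow = ntip + nnode, ncol = length(keep))
  for (i in seq_len(ntip)) {
    sets[i, ] <- .bit_of[tipmat[i, keep]]
  }
  post <- ape::reorder.phylo(phylo, "postorder")
  pe <- post$edge
  # up-pass: children of each internal node arrive consecutively in postorder
  done <- rep(FALSE, ntip + nnode)
  for (e in seq_len(nrow(pe))) {
    par <- pe[e, 1L]
    ch <- pe[e, 2L]
    if (!done[par]) {
      sets[par, ] <- sets[ch, ]
      done[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[ch, ])
      un <- bitwOr(sets[par, ], sets[ch, ])
      sets[par, ] <- ifelse(inter > 0L, inter, un)
    }
  }
  # down-pass resolution to single states
  states <- matrix("", nrow = ntip + nnode, ncol = length(keep))
  root <- ntip + 1L
  states[root, ] <- .lowbit_base[sets[root, ]]
  ce <- phylo$edge # cladewise = parents before children
  for (e in seq_len(nrow(ce))) {
    par <- ce[e, 1L]
    ch <- ce[e, 2L]
    pstate <- states[par, ]
    has_par <- bitwAnd(sets[ch, ], .bit_of[pstate]) > 0L
    states[ch, ] <- ifelse(has_par, pstate, .lowbit_base[sets[ch, ]])
  }
  seqs <- vapply(seq_len(ntip + nnode), function(i) {
    full <- rep("-", n)
    full[keep] <- states[i, ]
    paste0(full, collapse = "")
  }, "")
  names(seqs) <- lab
  structure(
    list(
      sequences = seqs, excluded_columns = excluded,
      gene_id = alignment$gene_id, tree = tree
    ),
    class = "ancestral_rec"
  )
}

#' @export
print.ancestral_rec <- function(x, ...) {
  cat(sprintf(
    "<ancestral_rec> %s: %d node sequences, %d column(s) excluded\n",
    x$gene_id, length(x$sequences), length(x$excluded_columns)
  ))
  invisible(x)
}

# Parent/child sequences for every branch, as a tibble joined to the branch
# annotations; used by the substitution spectrum and dN/dS counting.
edge_sequences <- function(rec) {
  br <- branch_table(rec$tree)
  lab <- node_labels(rec$tree$phylo)
  br$parent_seq <- unname(rec$sequences[lab[br$parent]])
  br$child_seq <- unname(rec$sequences[lab[br$child]])
  br$gene <- rec$gene_id
  br
}
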