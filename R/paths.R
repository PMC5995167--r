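# Orderings of k positions (k <= 3), as a list of integer vectors.
.perms <- function(v) {
  k <- length(v)
  if (k <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_len(k)) {
    for (rest in .perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Enumerate all mutational paths between two sense codons: one path per
# ordering of the changed positions, stepping one nucleotide at a time.
# Paths whose intermediate codons are stops are invalid ("through sense
# codons"). Returns the valid paths (each a list of step records), the
# number of orderings and the number of valid ones. Memoised.
codon_paths <- function(c1, c2, code = genetic_code()) {
  key <- paste0("paths:", rlang::hash(code), ":", c1, ":", c2)
  hit <- .asexdiv_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  b1 <- strsplit(c1, "")[[1L]]
  b2 <- strsplit(c2, "")[[1L]]
  diffs <- which(b1 != b2)
  orderings <- .perms(diffs)
  paths <- list()
  for (ord in orderings) {
    cur <- b1
    steps <- vector("list", length(ord))
    valid <- TRUE
    for (s in seq_along(ord)) {
      p <- ord[s]
      nxt <- cur
      nxt[p] <- b2[p]
      from_codon <- paste0(cur, collapse = "")
      to_codon <- paste0(nxt, collapse = "")
      if (code[[to_codon]] == "*") {
        valid <- FALSE
        break
      }
      steps[[s]] <- list(
        pos = p, from_base = cur[p], to_base = b2[p],
        synonymous = code[[from_codon]] == code[[to_codon]],
        class = change_class(cur[p], b2[p])
      )
      cur <- nxt
    }
    if (valid) paths[[length(paths) + 1L]] <- steps
  }
  out <- list(paths = paths, n_orderings = length(orderings), n_valid = length(paths))
  assign(key, out, envir = .asexdiv_cache)
  out
}

# Nei-Gojobori style observed differences between two sense codons:
# nonsynonymous and synonymous step counts averaged over all valid paths.
# NULL when no stop-free path exists (codon pair excluded).
codon_pair_counts <- function(c1, c2, code = genetic_code()) {
  if (c1 == c2) {
    return(c(nd = 0, sd = 0))
  }
  cp <- codon_paths(c1, c2, code)
  if (cp$n_valid == 0L) {
    return(NULL)
  }
  nd <- vapply(cp$paths, function(p) sum(!vapply(p, `[[`, TRUE, "synonymous")), 0)
  sd <- vapply(cp$paths, function(p) sum(vapply(p, `[[`, TRUE, "synonymous")), 0)
  c(nd = mean(nd), sd = mean(sd))
}

# Fractional synonymous site count per codon (Nei-Gojobori): at each
# position, the fraction of the three possible changes that are synonymous;
# changes creating stops count as nonsynonymous, so S + N = 3 per codon.
syn_site_fraction <- function(code = genetic_code()) {
  key <- paste0("synfrac:", rlang::hash(code))
  hit <- .asexdiv_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  nb <- codon_neighbors(code)
  agg <- tapply(nb$synonymous, nb$from, sum)
  out <- stats::setNames(rep(NA_real_, 64L), CODONS)
  out[names(agg)] <- agg / 3
  assign(key, out, envir = .asexdiv_cache)
  out
}

#' Nei--Gojobori synonymous and nonsynonymous site counts
#'
#' Fractional site counts over a coding sequence: for every codon and
#' position, the synonymous "site fraction" is the share of the three
#' possible single-nucleotide changes that preserve the amino acid, with
#' stop-creating changes counted as nonsynonymous. Consequently
#' `N_sites + S_sites = 3 * n_codons` over the codons counted. Codons
#' containing gaps or ambiguity codes are skipped.
#'
#' @param seq Coding sequence (string).
#' @param code Genetic code.
#' @return A named numeric vector `c(N_sites, S_sites, n_codons)`.
#' @export
ng86_sites <- function(seq, code = genetic_code()) {
  sfrac <- syn_site_fraction(code)
  codons <- split_codons(seq)
  s <- sfrac[codons]
  s <- s[!is.na(s)]
  c(N_sites = 3 * length(s) - sum(s), S_sites = sum(s), n_codons = length(s))
}
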