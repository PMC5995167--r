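BASES <- c("A", "C", "G", "T")

# All 64 codons, first position varying slowest (AAA, AAC, ..., TTT).
CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
CODONS <- sort(CODONS)

#' The genetic code used throughout the package
#'
#' Returns the standard nuclear genetic code (NCBI translation table 1) as a
#' named character vector mapping each of the 64 codons to a one-letter amino
#' acid, with `"*"` marking stop codons. All codon-level operations in the
#' package take a `code` argument so that alternative code tables can be
#' injected, e.g. for testing.
#'
#' @return A named character vector of length 64 (names are codons).
#' @examples
#' code <- genetic_code()
#' code["ATG"]
#' sum(code == "*")
#' @export
genetic_code <- function() {
  hit <- .asexdiv_cache[["standard_code"]]
  if (!is.null(hit)) {
    return(hit)
  }
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[CODONS])
  names(out) <- CODONS
  assign("standard_code", out, envir = .asexdiv_cache)
  out
}

#' Sense codons of a genetic code
#' @param code A genetic code as returned by [genetic_code()].
#' @return Character vector of codons that do not encode a stop.
#' @export
sense_codons <- function(code = genetic_code()) {
  names(code)[code != "*"]
}

translate_codons <- function(codons, code = genetic_code()) {
  unname(code[codons])
}

#' Fold degeneracy of codon positions
#'
#' For every sense codon and codon position, the fold class is the number of
#' nucleotides at that position (including the observed one) that encode the
#' same amino acid: 1 (non-degenerate) through 4 (fourfold degenerate).
#' Classifying a segregating site by the fold degeneracy of its position is
#' the standard first step when separating synonymous from nonsynonymous
#' variants.
#'
#' @inheritParams sense_codons
#' @return An integer matrix with one row per codon (rownames are codons) and
#'   three columns; rows for stop codons are `NA`.
#' @examples
#' deg <- codon_degeneracy()
#' deg["GGA", ] # fourfold at position 3
#' deg["ATG", ] # Met: non-degenerate everywhere
#' @export
codon_degeneracy <- function(code = genetic_code()) {
  key <- paste0("degeneracy:", rlang::hash(code))
  hit <- .asexdiv_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  out <- matrix(NA_integer_, nrow = 64L, ncol = 3L, dimnames = list(CODONS, NULL))
  for (codon in sense_codons(code)) {
    aa <- code[[codon]]
    bases <- strsplit(codon, "")[[1L]]
    for (pos in 1:3) {
      alts <- vapply(BASES, function(b) {
        mut <- bases
        mut[pos] <- b
        code[[paste0(mut, collapse = "")]] == aa
      }, logical(1))
      out[codon, pos] <- sum(alts)
    }
  }
  assign(key, out, envir = .asexdiv_cache)
  out
}

# Direction class of a single-nucleotide change with respect to base
# "strength": weak (W) = A/T, strong (S) = G/C. W->S is "ws", S->W is "sw",
# and A<->T / G<->C are GC-conservative ("cons").
change_class <- function(from, to) {
  strong <- function(b) b %in% c("G", "C")
  dplyr::case_when(
    !strong(from) & strong(to) ~ "ws",
    strong(from) & !strong(to) ~ "sw",
    TRUE ~ "cons"
  )
}

is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

#' Single-nucleotide codon neighbourhood
#'
#' Enumerates every single-nucleotide change away from every sense codon,
#' annotated with the change position, transition/transversion status,
#' synonymy, strength class (W->S, S->W, GC-conservative) and whether the
#' target codon is a stop. This table underlies the codon substitution
#' simulator, Nei--Gojobori site counting and SNP effect classification.
#'
#' @inheritParams sense_codons
#' @return A tibble with columns `from`, `to`, `pos`, `from_base`, `to_base`,
#'   `transition`, `synonymous`, `to_stop`, `class`.
#' @export
codon_neighbors <- function(code = genetic_code()) {
  sense <- sense_codons(code)
  rows <- lapply(sense, function(codon) {
    bases <- strsplit(codon, "")[[1L]]
    out <- vector("list", 9L)
    k <- 0L
    for (pos in 1:3) {
      for (b in setdiff(BASES, bases[pos])) {
        mut <- bases
        mut[pos] <- b
        to <- paste0(mut, collapse = "")
        k <- k + 1L
        out[[k]] <- tibble(
          from = codon, to = to, pos = pos,
          from_base = bases[pos], to_base = b
        )
      }
    }
    dplyr::bind_rows(out)
  })
  nb <- dplyr::bind_rows(rows)
  nb$transition <- is_transition(nb$from_base, nb$to_base)
  nb$to_stop <- code[nb$to] == "*"
  nb$synonymous <- !nb$to_stop & code[nb$from] == code[nb$to]
  nb$class <- change_class(nb$from_base, nb$to_base)
  nb
}
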