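#' IUPAC degenerate nucleotide codes
#'
#' Named list mapping each of the 15 IUPAC nucleotide symbols to the set of
#' concrete bases it stands for (e.g. `Y` = C/T, `S` = C/G, `N` = A/C/G/T).
#'
#' @format Named list of character vectors.
#' @export
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Validate an IUPAC consensus string
#'
#' Checks that `consensus` is a single non-empty string over the 15 IUPAC
#' nucleotide codes. Invalid symbols raise an error naming the first offending
#' position.
#'
#' @param consensus Character scalar, e.g. `"TATCCAY"`.
#' @param min_length Minimum accepted length (default 1).
#' @return The consensus, invisibly, upper-cased.
#' @export
validate_consensus <- function(consensus, min_length = 1L) {
  if (!is.character(consensus) || length(consensus) != 1L || is.na(consensus))
    stop("consensus must be a single character string")
  consensus <- toupper(consensus)
  if (nchar(consensus) < min_length)
    stop("consensus '", consensus, "' is shorter than ", min_length)
  sym <- strsplit(consensus, "")[[1]]
  bad <- which(!sym %in% names(IUPAC_NT))
  if (length(bad))
    stop("invalid IUPAC symbol '", sym[bad[1]], "' at position ", bad[1],
         " of consensus '", consensus, "'")
  invisible(consensus)
}

#' Per-symbol degeneracy and total expansion size of a consensus
#'
#' @param consensus IUPAC consensus string.
#' @return Integer: the product of per-symbol degeneracies, i.e. the number of
#'   concrete words the consensus stands for.
#' @export
iupac_degeneracy <- function(consensus) {
  validate_consensus(consensus)
  sym <- strsplit(toupper(consensus), "")[[1]]
  prod(vapply(IUPAC_NT[sym], length, integer(1)))
}

#' Expand an IUPAC consensus to its concrete words
#'
#' Enumerates every concrete DNA word matching the consensus. The expansion
#' size equals the product of per-symbol degeneracies; `limit` guards against
#' accidental explosion with N-rich consensi.
#'
#' @param consensus IUPAC consensus string.
#' @param limit Maximum number of words to enumerate (default 65536).
#' @return Character vector of concrete words over A/C/G/T.
#' @examples
#' iupac_expand("TATCCAY")   # TATCCAC, TATCCAT
#' length(iupac_expand("ACGTSSSC"))  # 8
#' @export
iupac_expand <- function(consensus, limit = 65536L) {
  validate_consensus(consensus)
  consensus <- toupper(consensus)
  n <- iupac_degeneracy(consensus)
  if (n > limit)
    stop("expansion of '", consensus, "' has ", n, " words, above limit ", limit)
  sym <- strsplit(consensus, "")[[1]]
  words <- do.call(expand.grid,
                   c(rev(unname(IUPAC_NT[sym])),
                     list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  words <- words[, rev(seq_along(sym)), drop = FALSE]
  sort(apply(as.matrix(words), 1L, paste0, collapse = ""))
}

#' Predicate matcher for an IUPAC consensus
#'
#' Returns a function testing whether concrete words satisfy the consensus
#' (same-length words over A/C/G/T; anything else, including N on the word
#' side, does not match).
#'
#' @param consensus IUPAC consensus string.
#' @return Function: character vector of words -> logical vector.
#' @export
iupac_matcher <- function(consensus) {
  validate_consensus(consensus)
  consensus <- toupper(consensus)
  sets <- IUPAC_NT[strsplit(consensus, "")[[1]]]
  w <- length(sets)
  function(words) {
    vapply(toupper(words), function(word) {
      if (nchar(word) != w) return(FALSE)
      ch <- strsplit(word, "")[[1]]
      all(mapply(function(s, b) b %in% s, sets, ch))
    }, logical(1), USE.NAMES = FALSE)
  }
}

#' Reverse complement of an IUPAC consensus
#'
#' Degenerate symbols complement to their partner code (Y <-> R, S <-> S, ...).
#'
#' @param consensus IUPAC consensus string.
#' @return The reverse-complemented consensus string.
#' @export
revcomp_consensus <- function(consensus) {
  validate_consensus(consensus)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(consensus))))
}

#' Single-window match probability of a consensus under an i.i.d. GC model
#'
#' Probability that one window of i.i.d. background sequence (P(C) = P(G) =
#' gc/2, P(A) = P(T) = (1-gc)/2) satisfies the consensus on the forward strand.
#'
#' @param consensus IUPAC consensus string.
#' @param gc GC fraction of the background model.
#' @return Probability in \[0, 1\].
#' @export
iupac_match_prob <- function(consensus, gc) {
  validate_consensus(consensus)
  stopifnot(gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sets <- IUPAC_NT[strsplit(toupper(consensus), "")[[1]]]
  prod(vapply(sets, function(s) sum(p[s]), numeric(1)))
}

#' Union bound on the probability a consensus occurs in a background sequence
#'
#' Upper-bounds P(at least one hit) for a motif scanned against an i.i.d.
#' background sequence of given length, by the expected hit count
#' (windows x per-window probability, summed over the scanned strands).
#' Used to bound the rate at which background motifs contaminate group-unique
#' CRE sets.
#'
#' @param consensus IUPAC consensus string.
#' @param seq_length Background sequence length in bp.
#' @param gc GC fraction.
#' @param both_strands Scan both strands (default TRUE)?
#' @return Upper bound on the presence probability, capped at 1.
#' @export
motif_presence_bound <- function(consensus, seq_length, gc, both_strands = TRUE) {
  w <- nchar(consensus)
  if (seq_length < w) return(0)
  windows <- seq_length - w + 1L
  p <- iupac_match_prob(consensus, gc)
  if (both_strands) p <- p + iupac_match_prob(revcomp_consensus(consensus), gc)
  min(1, windows * p)
}
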