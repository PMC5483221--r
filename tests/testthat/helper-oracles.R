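# Independent oracles used across the suite. These deliberately avoid the
# package's scanning/alignment code paths: the scanner oracle expands the
# consensus to concrete words and substring-searches each with regex
# lookahead; the alignment oracle enumerates all global alignments
# recursively.

rand_dna <- function(len, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Reverse complement for plain character DNA (oracle-side, no Biostrings).
rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# All overlapping 0-based start positions of fixed word `w` in `s`.
word_starts <- function(w, s) {
  m <- gregexpr(paste0("(?=", w, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Brute-force IUPAC scan: expand the consensus, substring-search every word on
# both strands; minus-strand hits are matches of the reverse-complemented
# words, reported at forward coordinates.
oracle_scan <- function(sequence, consensus) {
  words <- iupac_expand(consensus)
  plus <- sort(unique(unlist(lapply(words, word_starts, s = sequence))))
  rc_words <- vapply(words, rc_chr, character(1))
  minus <- sort(unique(unlist(lapply(rc_words, word_starts, s = sequence))))
  list(plus = plus, minus = minus)
}

# Brute-force global alignment score: match/mismatch from `mat`, linear gap
# cost `gap` per gap position. Exponential; only for tiny sequences.
oracle_nw_score <- function(a, b, mat, gap) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i > length(a) && j > length(b)) 0
    else if (i > length(a)) -gap * (length(b) - j + 1)
    else if (j > length(b)) -gap * (length(a) - i + 1)
    else max(mat[a[i], b[j]] + rec(i + 1, j + 1),
             rec(i + 1, j) - gap,
             rec(i, j + 1) - gap)
    memo[[key]] <- v
    v
  }
  rec(1, 1)
}

# Uniform match/mismatch substitution matrix over the 20 amino acids.
toy_aa_matrix <- function(match = 1, mismatch = -1) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- matrix(mismatch, 20, 20, dimnames = list(aa, aa))
  diag(m) <- match
  m
}

# Random unrooted binary tree with uniform branch lengths; returns ape phylo.
rand_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  tr
}
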