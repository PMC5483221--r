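#' Scan one sequence with a degenerate IUPAC consensus
#'
#' Tests every window of the sequence (all overlapping windows are reported).
#' Degenerate symbols in the consensus match their IUPAC base sets; `N` in the
#' *sequence* is treated as missing data and matches nothing. Minus-strand
#' hits are matches of the reverse-complemented consensus and are reported at
#' forward-strand coordinates of the window, with the forward-strand substring
#' in `match`.
#'
#' @param sequence A single DNA sequence: character scalar or
#'   [Biostrings::DNAString].
#' @param consensus IUPAC consensus string.
#' @param name Motif name recorded in the output (defaults to the consensus).
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return A data.frame with columns `motif`, `start` (0-based), `end`
#'   (half-open), `strand` and `match`; zero rows when nothing matches or the
#'   sequence is shorter than the consensus.
#' @examples
#' scan_sequence("AAATATCCACAA", "TATCCAY")           # one + hit at start 3
#' scan_sequence("GTGGATA", "TATCCAY")                # one - hit
#' @export
scan_sequence <- function(sequence, consensus, name = consensus,
                          strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  validate_consensus(consensus, min_length = 1L)
  if (!methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAString(toupper(as.character(sequence)))
  w <- nchar(consensus)
  hits <- list()
  if (strands %in% c("both", "plus") && length(sequence) >= w) {
    m <- Biostrings::matchPattern(toupper(consensus), sequence, fixed = "subject")
    if (length(m))
      hits[["+"]] <- data.frame(
        motif = name, start = BiocGenerics::start(m) - 1L,
        end = BiocGenerics::end(m), strand = "+",
        match = as.character(m), stringsAsFactors = FALSE)
  }
  if (strands %in% c("both", "minus") && length(sequence) >= w) {
    rc <- revcomp_consensus(consensus)
    m <- Biostrings::matchPattern(rc, sequence, fixed = "subject")
    if (length(m))
      hits[["-"]] <- data.frame(
        motif = name, start = BiocGenerics::start(m) - 1L,
        end = BiocGenerics::end(m), strand = "-",
        match = as.character(m), stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  # N (or any ambiguity code) in the sequence is missing data and matches
  # nothing -- including a pattern N, which Biostrings would let through
  out <- out[!grepl("[^ACGT]", out$match), , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set with a motif library
#'
#' @param promoters Named [Biostrings::DNAStringSet] (names are gene ids) or a
#'   `promoter_set` object from [gen_promoter_set()].
#' @param library Motif library data.frame (columns `name`, `consensus`).
#' @param strands Strand policy, as in [scan_sequence()].
#' @return A data.frame of hits with an additional `gene_id` column.
#' @export
scan_promoters <- function(promoters, library, strands = "both") {
  seqs <- as_promoter_seqs(promoters)
  out <- lapply(seq_along(seqs), function(i) {
    per_gene <- lapply(seq_len(nrow(library)), function(j)
      scan_sequence(seqs[[i]], library$consensus[j], name = library$name[j],
                    strands = strands))
    per_gene <- do.call(rbind, per_gene)
    if (nrow(per_gene)) per_gene$gene_id <- names(seqs)[i]
    else per_gene$gene_id <- character(0)
    per_gene
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("motif", "gene_id", "start", "end", "strand", "match")]
}

#' Motif x promoter incidence matrix
#'
#' Complete hit-count matrix (explicit zeros) for a motif library against a
#' promoter set, counting all overlapping hits on the scanned strands. Row
#' order follows the library, column order follows the input promoters.
#'
#' @inheritParams scan_promoters
#' @return Integer matrix, motifs x genes, with dimnames.
#' @export
build_incidence <- function(promoters, library, strands = "both") {
  seqs <- as_promoter_seqs(promoters)
  if (length(seqs) == 0L || nrow(library) == 0L)
    stop("build_incidence requires non-empty promoters and library")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("promoters must carry unique gene ids as names")
  counts <- matrix(0L, nrow(library), length(seqs),
                   dimnames = list(library$name, ids))
  # fast path: sequences free of ambiguity codes cannot produce the
  # N-matches-N artifact, so plain counting is exact
  af <- Biostrings::alphabetFrequency(seqs)
  clean <- sum(af[, c("A", "C", "G", "T"), drop = FALSE]) ==
    sum(Biostrings::width(seqs))
  for (j in seq_len(nrow(library))) {
    cons <- toupper(library$consensus[j])
    validate_consensus(cons)
    if (clean) {
      n <- Biostrings::vcountPattern(cons, seqs, fixed = "subject")
      if (strands == "both")
        n <- n + Biostrings::vcountPattern(revcomp_consensus(cons), seqs,
                                           fixed = "subject")
      counts[j, ] <- as.integer(n)
    } else {
      counts[j, ] <- vapply(seq_along(seqs), function(i)
        nrow(scan_sequence(seqs[[i]], cons, strands = strands)), integer(1))
    }
  }
  counts
}

# Coerce a promoter_set or DNAStringSet or named character vector to a
# named DNAStringSet.
as_promoter_seqs <- function(promoters) {
  if (inherits(promoters, "promoter_set")) return(promoters$sequences)
  if (methods::is(promoters, "DNAStringSet")) return(promoters)
  if (is.character(promoters)) {
    s <- Biostrings::DNAStringSet(toupper(promoters))
    names(s) <- names(promoters)
    return(s)
  }
  stop("cannot interpret 'promoters' as a promoter set")
}

#' Convert 0-based scan coordinates to ATG-relative positions
#'
#' Promoter sequences are upstream regions (length `upstream_len`) optionally
#' followed by the first intron or exon. Reports use the field convention of
#' 1-based negative upstream coordinates: -1 is the base immediately before
#' the ATG, -`upstream_len` the 5' end; positions at or after the ATG are
#' 1-based positive.
#'
#' @param start0 0-based start on the concatenated promoter sequence.
#' @param upstream_len Length of the upstream part in bp.
#' @return Integer ATG-relative position.
#' @export
atg_relative <- function(start0, upstream_len) {
  ifelse(start0 < upstream_len, start0 - upstream_len, start0 - upstream_len + 1L)
}

#' Write motif hits as TSV or GFF3
#'
#' GFF3 output uses feature type `nucleotide_motif`, 1-based coordinates on
#' the promoter sequence (seqid = gene id), and carries the motif name in
#' `Name`.
#'
#' @param hits Hit data.frame from [scan_promoters()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_gff3 <- function(hits, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$gene_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  gr$type <- "nucleotide_motif"
  gr$Name <- hits$motif
  gr$sequence <- hits$match
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
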