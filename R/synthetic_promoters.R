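#' Generate promoter sets with planted group-specific motifs
#'
#' Builds two disjoint promoter groups (sizes `group_sizes`) of i.i.d.
#' background sequence at the configured GC content. Each group receives
#' `planted_motifs_per_group` motifs from the library; every promoter of a
#' group carries one planted (concretely instantiated) copy of each of its
#' group's motifs at a recorded position on the + strand. When the library
#' contains the 13 default elements, group A draws from the
#' seed/endosperm-associated motifs and group B from the root/embryo-associated
#' ones; otherwise disjoint sets are sampled at random.
#'
#' Cross-group purity is enforced by construction: after planting, each
#' promoter is scanned (both strands) for the *other* group's planted motifs
#' and any accidental background hit is rejection-resampled (the offending
#' background window is redrawn; planted windows are never edited, and an
#' accidental hit straddling a planted window triggers a full re-draw of the
#' promoter's insert positions). Planted truth therefore holds exactly:
#' every planted motif occurs in every promoter of its group and never in the
#' other group's promoters.
#'
#' @param config A [synth_config()].
#' @param library Motif library data.frame (default: the 13 elements plus
#'   `config$n_decoy_motifs` decoys).
#' @param gene_ids Optional list with character vectors `A` and `B` naming the
#'   promoters (defaults to `grpA_01`, ...).
#' @return List with elements:
#'   \describe{
#'     \item{promoters}{`promoter_set` object: `sequences` (named
#'       [Biostrings::DNAStringSet]) and `regions` data.frame}
#'     \item{groups}{list of gene-id vectors `A`, `B`}
#'     \item{truth}{list: `motif_groups` (data.frame motif, group) and
#'       `positions` (data.frame gene_id, motif, start, strand, match)}
#'     \item{library}{the scanned motif library}
#'   }
#' @export
gen_promoter_set <- function(config = synth_config(), library = NULL,
                             gene_ids = NULL) {
  validate_synth_config(config)
  set.seed(config$seed + 1L)
  if (is.null(library))
    library <- gen_motif_library(config$n_decoy_motifs, seed = config$seed + 2L)
  L <- config$promoter_length + config$extra_length
  k <- config$planted_motifs_per_group
  too_long <- library$consensus[nchar(library$consensus) > L]
  if (length(too_long))
    stop("motif longer than promoter: ", paste(too_long, collapse = ", "))

  defaults <- default_motif_library()$name
  if (k > 0 && all(defaults %in% library$name)) {
    if (k > length(seed_motif_names()) || k > length(root_motif_names()))
      stop("planted_motifs_per_group exceeds the per-group default motif pools")
    motifs_a <- sample(seed_motif_names(), k)
    motifs_b <- sample(root_motif_names(), k)
  } else if (k > 0) {
    if (2 * k > nrow(library))
      stop("library too small for two disjoint planted sets of size ", k)
    pick <- sample(library$name, 2 * k)
    motifs_a <- pick[seq_len(k)]
    motifs_b <- pick[k + seq_len(k)]
  } else {
    motifs_a <- motifs_b <- character(0)
  }

  if (is.null(gene_ids))
    gene_ids <- list(A = sprintf("grpA_%02d", seq_len(config$group_sizes[1])),
                     B = sprintf("grpB_%02d", seq_len(config$group_sizes[2])))
  stopifnot(length(gene_ids$A) == config$group_sizes[1],
            length(gene_ids$B) == config$group_sizes[2])

  consensus_of <- stats::setNames(library$consensus, library$name)
  base_prob <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                 G = config$gc_content / 2, T = (1 - config$gc_content) / 2)

  make_promoter <- function(own_motifs, other_motifs) {
    for (attempt in seq_len(50L)) {
      bases <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
      planted <- plant_motifs(bases, consensus_of[own_motifs], L)
      if (is.null(planted)) next
      bases <- planted$bases
      repaired <- repair_cross_hits(bases, consensus_of[other_motifs],
                                    planted$intervals, base_prob)
      if (is.null(repaired)) next   # hit straddled a planted window: re-draw
      return(list(bases = repaired, positions = planted$positions))
    }
    stop("failed to generate a purity-compliant promoter in 50 attempts")
  }

  seqs <- character(0); pos_rows <- list()
  for (g in c("A", "B")) {
    own <- if (g == "A") motifs_a else motifs_b
    other <- if (g == "A") motifs_b else motifs_a
    for (id in gene_ids[[g]]) {
      p <- make_promoter(own, other)
      seqs[[id]] <- paste0(p$bases, collapse = "")
      if (length(own))
        pos_rows[[id]] <- data.frame(
          gene_id = id, motif = names(p$positions),
          start = unname(p$positions) - 1L, strand = "+",
          match = vapply(names(p$positions), function(m) {
            w <- nchar(consensus_of[m])
            substr(seqs[[id]], p$positions[m], p$positions[m] + w - 1L)
          }, character(1)),
          stringsAsFactors = FALSE)
    }
  }

  sequences <- Biostrings::DNAStringSet(seqs)
  regions <- data.frame(gene_id = names(seqs),
                        upstream_len = config$promoter_length,
                        extra_len = config$extra_length,
                        group = rep(c("A", "B"), config$group_sizes),
                        stringsAsFactors = FALSE)
  positions <- if (length(pos_rows)) do.call(rbind, pos_rows) else
    data.frame(gene_id = character(0), motif = character(0),
               start = integer(0), strand = character(0),
               match = character(0), stringsAsFactors = FALSE)
  rownames(positions) <- NULL
  motif_groups <- data.frame(
    motif = c(motifs_a, motifs_b),
    group = rep(c("A", "B"), c(length(motifs_a), length(motifs_b))),
    stringsAsFactors = FALSE)

  list(promoters = structure(list(sequences = sequences, regions = regions),
                             class = "promoter_set"),
       groups = gene_ids,
       truth = list(motif_groups = motif_groups, positions = positions),
       library = library)
}

# Insert one concrete instance of each consensus at random non-overlapping
# positions. Returns NULL when non-overlapping placement fails (caller
# re-draws), else list(bases, positions (1-based starts, named by motif),
# intervals (list of c(start, end) 1-based closed)).
plant_motifs <- function(bases, consensi, L) {
  intervals <- list(); positions <- integer(0)
  for (m in names(consensi)) {
    w <- nchar(consensi[m])
    placed <- FALSE
    for (try in seq_len(100L)) {
      s <- sample.int(L - w + 1L, 1L)
      e <- s + w - 1L
      clash <- any(vapply(intervals, function(iv) s <= iv[2] && e >= iv[1],
                          logical(1)))
      if (!clash) {
        word <- sample(iupac_expand(consensi[m]), 1L)
        bases[s:e] <- strsplit(word, "")[[1]]
        intervals[[length(intervals) + 1L]] <- c(s, e)
        positions[m] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  list(bases = bases, positions = positions, intervals = intervals)
}

# Rejection-resample background windows that accidentally match any of the
# forbidden consensi (both strands). Planted intervals are protected; a
# forbidden hit overlapping one returns NULL so the caller re-draws insert
# positions. Returns the repaired base vector.
repair_cross_hits <- function(bases, forbidden, protected, base_prob,
                              max_rounds = 200L) {
  if (!length(forbidden)) return(bases)
  pats <- unique(c(toupper(forbidden),
                   vapply(unname(forbidden), revcomp_consensus, character(1))))
  for (round in seq_len(max_rounds)) {
    subject <- Biostrings::DNAString(paste0(bases, collapse = ""))
    clean <- TRUE
    for (pat in pats) {
      m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
      if (!length(m)) next
      ss <- BiocGenerics::start(m); ee <- BiocGenerics::end(m)
      for (h in seq_along(ss)) {
        s <- ss[h]; e <- ee[h]
        overlaps <- any(vapply(protected, function(iv) s <= iv[2] && e >= iv[1],
                               logical(1)))
        if (overlaps) return(NULL)
        bases[s:e] <- sample(names(base_prob), e - s + 1L, replace = TRUE,
                             prob = base_prob)
      }
      clean <- FALSE
    }
    if (clean) return(bases)
  }
  stop("purity repair did not converge in ", max_rounds, " rounds")
}

#' Write a promoter set as FASTA plus BED regions
#'
#' The BED file (0-based half-open) describes each promoter's upstream part
#' and, when present, its first-intron/exon part on the promoter's own
#' coordinate system.
#'
#' @param promoters A `promoter_set`.
#' @param fasta_path,bed_path Output paths.
#' @return The FASTA path, invisibly.
#' @export
write_promoter_set <- function(promoters, fasta_path, bed_path) {
  stopifnot(inherits(promoters, "promoter_set"))
  Biostrings::writeXStringSet(promoters$sequences, fasta_path)
  reg <- promoters$regions
  gr <- GenomicRanges::GRanges(
    seqnames = rep(reg$gene_id, ifelse(reg$extra_len > 0, 2L, 1L)),
    ranges = IRanges::IRanges(
      start = unlist(mapply(function(u, e) if (e > 0) c(1L, u + 1L) else 1L,
                            reg$upstream_len, reg$extra_len, SIMPLIFY = FALSE)),
      end = unlist(mapply(function(u, e) if (e > 0) c(u, u + e) else u,
                          reg$upstream_len, reg$extra_len, SIMPLIFY = FALSE))),
    name = unlist(mapply(function(g, e)
      if (e > 0) paste0(g, c("_upstream", "_intron_exon")) else paste0(g, "_upstream"),
      reg$gene_id, reg$extra_len, SIMPLIFY = FALSE)))
  rtracklayer::export.bed(gr, bed_path)
  invisible(fasta_path)
}

#' Read a promoter FASTA into a promoter set
#'
#' @param fasta_path Promoter FASTA (one record per gene).
#' @param upstream_len Upstream length in bp (recycled over genes).
#' @return A `promoter_set`.
#' @export
read_promoter_fasta <- function(fasta_path, upstream_len = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  len <- Biostrings::width(seqs)
  up <- if (is.null(upstream_len)) len else rep(upstream_len, length.out = length(seqs))
  structure(list(sequences = seqs,
                 regions = data.frame(gene_id = names(seqs),
                                      upstream_len = up,
                                      extra_len = len - up,
                                      group = NA_character_,
                                      stringsAsFactors = FALSE)),
            class = "promoter_set")
}
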