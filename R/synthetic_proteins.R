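AMINO_ACIDS <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Generate an aligned protein family evolved on a known subgroup tree
#'
#' Builds a true tree of `protein_clades` clades (each a random binary
#' subtree of `taxa_per_clade` taxa with short within-clade branches) hanging
#' off a central multifurcation by long stem branches, then evolves a random
#' ancestral sequence along it: per branch and site, a Poisson number of
#' substitutions (mean = branch length in substitutions/site), each replacing
#' the residue with a uniform draw from the other 19 amino acids. No indels
#' are introduced, so the emitted sequences are an alignment by construction.
#' Within-clade distances are below between-clade distances in expectation
#' whenever `stem_branch` exceeds `within_clade_branch`.
#'
#' @param config A [synth_config()].
#' @return List with elements:
#'   \describe{
#'     \item{alignment}{[Biostrings::AAStringSet], taxa named
#'       `<clade>_t<i>`}
#'     \item{true_tree}{the true tree as an [ape::phylo] (multifurcating at
#'       the backbone)}
#'     \item{subgroups}{named character vector taxon -> clade label
#'       (`clade1`...)}
#'   }
#' @export
gen_protein_family <- function(config = synth_config()) {
  validate_synth_config(config)
  if (config$protein_clades < 2L) stop("need >= 2 subgroup clades")
  set.seed(config$seed + 3L)

  clade_newick <- function(taxa, rate) {
    frags <- taxa
    while (length(frags) > 1L) {
      pick <- sample.int(length(frags), 2L)
      b <- stats::runif(2, 0.4 * rate, 1.6 * rate)
      merged <- sprintf("(%s:%.6f,%s:%.6f)", frags[pick[1]], b[1],
                        frags[pick[2]], b[2])
      frags <- c(frags[-pick], merged)
    }
    frags
  }

  clades <- sprintf("clade%d", seq_len(config$protein_clades))
  sub_frags <- vapply(clades, function(cl) {
    taxa <- sprintf("%s_t%d", cl, seq_len(config$taxa_per_clade))
    if (length(taxa) == 1L) taxa else clade_newick(taxa, config$within_clade_branch)
  }, character(1))
  newick <- paste0("(", paste0(sub_frags, sprintf(":%.6f", config$stem_branch),
                               collapse = ","), ");")
  true_tree <- ape::read.tree(text = newick)

  # evolve sequences root -> tips (preorder over the edge matrix)
  tr <- ape::reorder.phylo(true_tree, "cladewise")
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- sample(AMINO_ACIDS, config$protein_length, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    s <- seqs[[parent]]
    nsub <- stats::rpois(config$protein_length, b)
    for (i in which(nsub > 0))
      for (k in seq_len(nsub[i]))
        s[i] <- sample(setdiff(AMINO_ACIDS, s[i]), 1L)
    seqs[[child]] <- s
  }
  tip_seqs <- vapply(seq_len(n_tip), function(i) paste0(seqs[[i]], collapse = ""),
                     character(1))
  alignment <- Biostrings::AAStringSet(stats::setNames(tip_seqs, tr$tip.label))

  subgroups <- stats::setNames(sub("_t\\d+$", "", tr$tip.label), tr$tip.label)
  list(alignment = alignment, true_tree = true_tree, subgroups = subgroups)
}
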