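#' Alignment to character matrix
#'
#' Accepts an [Biostrings::AAStringSet], a named character vector of aligned
#' sequences, or a character matrix (taxa x columns), and returns the matrix
#' form. Rows must have equal lengths and unique names.
#' @param a Alignment in any accepted form.
#' @return Character matrix with taxon rownames.
#' @export
as_alignment_matrix <- function(a) {
  if (is.matrix(a)) {
    m <- a
  } else {
    if (methods::is(a, "XStringSet")) a <- stats::setNames(as.character(a), names(a))
    if (!is.character(a)) stop("cannot interpret alignment")
    if (length(unique(nchar(a))) != 1L) stop("aligned rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(a), ""))
    rownames(m) <- names(a)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment requires unique taxon names")
  m
}

#' p-distance matrix under complete deletion
#'
#' Removes every alignment column containing a gap (`-` or `.`) or `X` in any
#' row, then computes, on the shared retained-column set,
#' d(i, j) = mismatching columns / retained columns.
#'
#' @param a Alignment (see [as_alignment_matrix()]).
#' @return Symmetric numeric matrix with zero diagonal, taxon dimnames.
#' @export
p_distance_matrix <- function(a) {
  m <- as_alignment_matrix(a)
  if (nrow(m) < 3L) stop("need >= 3 taxa")
  keep <- colSums(m == "-" | m == "." | m == "X") == 0L
  if (!any(keep)) stop("complete deletion removed every column")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q-criterion. For an additive distance
#' matrix the path-length metric of the output reproduces the input exactly.
#' Ties in the Q matrix are broken deterministically in favor of the pair
#' whose subtrees contain the lexicographically smallest taxon ids. Negative
#' branch length estimates are clamped to zero with the deficit transferred to
#' the sibling branch, preserving the path length between the joined nodes.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree (basal trifurcation).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels                 # newick fragment per active node
  rep_id <- labels               # lexicographically smallest taxon in subtree
  D <- unname(d)

  clamp <- function(li, lj, dij) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_id[ij[1]], rep_id[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp(li, lj, D[i, j])
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], ll[1], frag[j], ll[2])
    new_rep <- min(rep_id[i], rep_id[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_id <- c(rep_id[keep], new_rep)
  }

  # closed-form resolution of the final three nodes
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    frag[1], l1, frag[2], l2, frag[3], l3)
  ape::read.tree(text = newick)
}

#' Canonical unrooted splits of a tree
#'
#' Each non-trivial bipartition is encoded as the sorted, comma-joined taxon
#' set on the side containing the alphabetically first taxon, making split
#' sets directly comparable across trees on the same taxa.
#'
#' @param tree An [ape::phylo].
#' @return Character vector of canonical split encodings (possibly empty).
#' @export
tree_splits <- function(tree) {
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  out <- character(0)
  for (s in pp) {
    side <- labs[s]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (!anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' complete-deletion p-distance NJ tree per replicate, and scores each
#' internal split of the full-alignment tree by the fraction of replicate
#' trees containing it. Replicate r uses seed `seed + r`, so supports are
#' reproducible and independent of execution order.
#'
#' @param a Alignment (see [as_alignment_matrix()]).
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Integer root seed.
#' @return List: `tree` (the full-alignment NJ tree), `supports` (named
#'   numeric vector in \[0, 1\] per canonical split; see [tree_splits()]).
#' @export
bootstrap_support <- function(a, replicates = 500L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- as_alignment_matrix(a)
  main <- nj_tree(p_distance_matrix(m))
  main_splits <- tree_splits(main)
  count <- stats::setNames(numeric(length(main_splits)), main_splits)
  for (r in seq_len(replicates)) {
    set.seed(as.integer(seed) + r)
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_tree <- try(nj_tree(p_distance_matrix(m[, cols, drop = FALSE])),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rs <- tree_splits(rep_tree)
    hit <- main_splits %in% rs
    count[hit] <- count[hit] + 1
  }
  list(tree = main, supports = count / replicates)
}

#' Assign taxa to subgroups by nearest labeled exemplar
#'
#' Each unlabeled taxon receives the label of the exemplar at minimal
#' path-length (branch-length sum) distance in the tree; exemplars keep their
#' own labels. Also reports, per label, whether its taxa form a connected
#' subtree (i.e. an unrooted split of the tree — monophyly).
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param exemplars Named character vector: names are exemplar taxon ids,
#'   values their subgroup labels.
#' @return List: `assignment` (data.frame `taxon`, `subgroup`, `is_exemplar`)
#'   and `monophyletic` (named logical per label).
#' @export
assign_subgroups <- function(tree, exemplars) {
  taxa <- tree$tip.label
  missing <- setdiff(names(exemplars), taxa)
  if (length(missing))
    stop("exemplar not in tree: ", paste(missing, collapse = ", "))
  pd <- ape::cophenetic.phylo(tree)
  ex_names <- names(exemplars)
  lab <- vapply(taxa, function(tx) {
    if (tx %in% ex_names) return(unname(exemplars[tx]))
    dvec <- pd[tx, ex_names]
    best <- ex_names[dvec == min(dvec)]
    unname(exemplars[sort(best)[1]])
  }, character(1))
  assignment <- data.frame(taxon = taxa, subgroup = unname(lab),
                           is_exemplar = taxa %in% ex_names,
                           stringsAsFactors = FALSE)
  splits <- tree_splits(tree)
  anchor <- sort(taxa)[1]
  mono <- vapply(unique(lab), function(lb) {
    members <- sort(taxa[lab == lb])
    if (length(members) <= 1L || length(members) >= length(taxa) - 1L)
      return(TRUE)
    enc <- if (anchor %in% members) paste(members, collapse = ",") else
      paste(sort(setdiff(taxa, members)), collapse = ",")
    enc %in% splits
  }, logical(1))
  list(assignment = assignment, monophyletic = mono)
}

#' Percent similarity from a global (Needleman-Wunsch) alignment
#'
#' Globally aligns two protein sequences and reports the percentage of
#' alignment columns whose residue pair has a positive substitution score;
#' gap columns count in the denominator.
#'
#' @param seq_a,seq_b Protein sequences (character scalars or AAString).
#' @param substitution_matrix Scoring matrix name (e.g. `"BLOSUM62"`, the
#'   default) or a numeric matrix.
#' @param gap_opening,gap_extension Gap penalties handed to the aligner
#'   (positive costs).
#' @return List: `percent_similarity` (0-100), `score`, `aligned_a`,
#'   `aligned_b`.
#' @export
pairwise_similarity <- function(seq_a, seq_b,
                                substitution_matrix = "BLOSUM62",
                                gap_opening = 10, gap_extension = 0.5) {
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  mat <- if (is.matrix(substitution_matrix)) substitution_matrix else
    get_subst_matrix(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos <- mapply(function(x, y) {
    if (x == "-" || y == "-") return(FALSE)
    mat[x, y] > 0
  }, a, b)
  list(percent_similarity = 100 * mean(pos),
       score = Biostrings::score(aln),
       aligned_a = paste0(a, collapse = ""),
       aligned_b = paste0(b, collapse = ""))
}

get_subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Write a tree with bootstrap supports as Newick
#'
#' Supports (fractions in \[0, 1\]) are written as integer percentages on the
#' matching internal nodes.
#'
#' @param bs Result of [bootstrap_support()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_supported_tree <- function(bs, path) {
  tree <- bs$tree
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(tree$tip.label)[1]
  n <- length(labs)
  node_lab <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) <= 1L || length(side) >= n - 1L) { node_lab[k] <- ""; next }
    if (!anchor %in% side) side <- setdiff(labs, side)
    enc <- paste(sort(side), collapse = ",")
    node_lab[k] <- if (enc %in% names(bs$supports))
      sprintf("%d", round(100 * bs$supports[[enc]])) else ""
  }
  tree$node.label <- node_lab
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param d Distance matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  tab <- data.frame(taxon = rownames(d), d, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
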