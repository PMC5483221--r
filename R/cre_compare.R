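#' Motifs common to a promoter group
#'
#' A motif is group-common when it has at least one hit in every member's
#' promoter (`mode = "all_members"`). The quorum mode relaxes this to
#' presence in at least `ceiling(quorum * group size)` members.
#'
#' @param incidence Motif x gene hit-count matrix from [build_incidence()].
#' @param members Character vector of the group's gene ids (>= 2).
#' @param mode `"all_members"` (default) or `"quorum"`.
#' @param quorum Member fraction required in quorum mode.
#' @return Character vector of motif names, in library (row) order.
#' @export
group_common <- function(incidence, members, mode = c("all_members", "quorum"),
                         quorum = 1) {
  mode <- match.arg(mode)
  missing <- setdiff(members, colnames(incidence))
  if (length(missing))
    stop("group member missing from incidence matrix: ",
         paste(missing, collapse = ", "))
  present <- incidence[, members, drop = FALSE] >= 1L
  need <- if (mode == "all_members") length(members) else
    ceiling(quorum * length(members))
  rownames(incidence)[rowSums(present) >= need]
}

#' Compare two groups' common-motif sets
#'
#' The group-unique sets are the set differences of the two group-common
#' sets; the shared set is their intersection. This is the arithmetic behind
#' calling candidate elements for divergent expression of tandem duplicates:
#' elements conserved across both groups cannot explain the divergence and
#' are removed.
#'
#' @param common_a,common_b Character vectors of group-common motif names.
#' @return List of class `cre_comparison`: `common_a`, `common_b`, `shared`,
#'   `unique_a`, `unique_b`.
#' @export
compare_groups <- function(common_a, common_b) {
  structure(list(common_a = common_a, common_b = common_b,
                 shared = intersect(common_a, common_b),
                 unique_a = setdiff(common_a, common_b),
                 unique_b = setdiff(common_b, common_a)),
            class = "cre_comparison")
}

#' @export
print.cre_comparison <- function(x, ...) {
  cat("CRE comparison: |common A| =", length(x$common_a),
      "| |common B| =", length(x$common_b),
      "| shared =", length(x$shared),
      "| unique A =", length(x$unique_a),
      "| unique B =", length(x$unique_b), "\n")
  invisible(x)
}

#' Rank motifs by total hit count within a group
#'
#' @param incidence Motif x gene hit-count matrix.
#' @param motifs Motif names to rank (subset of incidence rows).
#' @param members Group gene ids.
#' @return data.frame `motif`, `count`, counts non-increasing, ties broken by
#'   motif name.
#' @export
rank_frequency <- function(incidence, motifs, members) {
  bad <- setdiff(motifs, rownames(incidence))
  if (length(bad)) stop("motifs not in incidence: ", paste(bad, collapse = ", "))
  if (!length(motifs))
    return(data.frame(motif = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  counts <- rowSums(incidence[motifs, members, drop = FALSE])
  ord <- order(-counts, motifs)
  data.frame(motif = motifs[ord], count = as.integer(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a CRE comparison report (TSV + JSON summary)
#'
#' The TSV has one row per motif appearing in either group-common set, with
#' membership flags and within-group total counts.
#'
#' @param comparison A `cre_comparison` from [compare_groups()].
#' @param incidence Motif x gene hit-count matrix.
#' @param members_a,members_b Group gene ids.
#' @param tsv_path,json_path Output files.
#' @return The TSV path, invisibly.
#' @export
write_cre_report <- function(comparison, incidence, members_a, members_b,
                             tsv_path, json_path) {
  motifs <- union(comparison$common_a, comparison$common_b)
  tab <- data.frame(
    motif = motifs,
    in_common_a = motifs %in% comparison$common_a,
    in_common_b = motifs %in% comparison$common_b,
    shared = motifs %in% comparison$shared,
    unique_a = motifs %in% comparison$unique_a,
    unique_b = motifs %in% comparison$unique_b,
    count_a = as.integer(rowSums(incidence[motifs, members_a, drop = FALSE])),
    count_b = as.integer(rowSums(incidence[motifs, members_b, drop = FALSE])),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_common_a = length(comparison$common_a),
         n_common_b = length(comparison$common_b),
         n_shared = length(comparison$shared),
         n_unique_a = length(comparison$unique_a),
         n_unique_b = length(comparison$unique_b),
         unique_a = comparison$unique_a,
         unique_b = comparison$unique_b),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(tsv_path)
}

#' Read a group-membership TSV (columns: gene_id, group)
#'
#' @param path File path.
#' @return Named list of gene-id vectors, one per group label.
#' @export
read_group_file <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "group") %in% names(tab)))
    stop("group file must have columns 'gene_id' and 'group'")
  split(tab$gene_id, tab$group)
}
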