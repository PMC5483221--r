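#' Construct an expression set (log2 intensities + tissue map)
#'
#' The core expression container: a genes x samples matrix of log2-normalized
#' intensities plus a sample -> tissue map. Missing values are disallowed;
#' upstream readers must impute or drop incomplete probes before building the
#' object.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames), all values finite.
#' @param tissue_map Character vector of tissue labels, named by sample id (or
#'   unnamed of length `ncol(values)`, taken in column order).
#' @return An object of class `expr_set`: list with elements `values` and
#'   `tissue_map`.
#' @export
expression_set <- function(values, tissue_map) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene ids as rownames")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique sample ids as colnames")
  if (any(!is.finite(values)))
    stop("expression values must all be finite (impute or drop upstream)")
  if (is.null(names(tissue_map))) {
    if (length(tissue_map) != ncol(values))
      stop("unnamed tissue_map must have one label per sample")
    names(tissue_map) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(tissue_map))
  if (length(missing))
    stop("samples without a tissue label: ", paste(missing, collapse = ", "))
  structure(list(values = values,
                 tissue_map = tissue_map[colnames(values)]),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      length(unique(x$tissue_map)), "tissues\n")
  invisible(x)
}

#' Per-tissue mean profiles
#'
#' Averages each gene's samples within each tissue, producing the
#' meta-expression profile matrix used for heat maps and pattern
#' classification.
#'
#' @param x An [expression_set()].
#' @return Numeric matrix, genes x tissues (tissue order = first appearance in
#'   the sample map).
#' @export
aggregate_tissue_means <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  tissues <- unique(unname(x$tissue_map))
  empty <- setdiff(tissues, unique(x$tissue_map))
  if (length(empty)) stop("tissue with zero samples: ", paste(empty, collapse = ", "))
  prof <- vapply(tissues, function(t) {
    cols <- which(x$tissue_map == t)
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  prof <- matrix(prof, nrow = nrow(x$values),
                 dimnames = list(rownames(x$values), tissues))
  prof
}

#' Classify tissue expression patterns
#'
#' Each gene is called `suppressed` when its maximum tissue mean is below
#' `floor`; `tissue-preferential` when the gap between the maximum tissue mean
#' and the median of the remaining tissue means is at least `delta` (the
#' preferred tissue is the argmax, ties resolved to the lexicographically
#' smallest tissue label so the call is invariant to column order); otherwise
#' `ubiquitous`. The specificity score is the max-minus-median-of-rest gap in
#' log2 units.
#'
#' @param profiles Genes x tissues matrix from [aggregate_tissue_means()].
#' @param delta Log2 gap required to call a preferential pattern (default 2).
#' @param floor Log2 level below which a gene is called suppressed (default 6).
#' @return data.frame with columns `gene_id`, `class`, `preferred_tissue`
#'   (NA unless preferential) and `score`.
#' @export
classify_pattern <- function(profiles, delta = 2.0, floor = 6.0) {
  if (ncol(profiles) < 2) stop("classification needs >= 2 tissues")
  tissues <- colnames(profiles)
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    v <- profiles[i, ]
    top_t <- sort(tissues[v == max(v)])[1]
    score <- max(v) - stats::median(v[tissues != top_t])
    if (max(v) < floor) {
      cls <- "suppressed"; pref <- NA_character_
    } else if (score >= delta) {
      cls <- "tissue-preferential"; pref <- top_t
    } else {
      cls <- "ubiquitous"; pref <- NA_character_
    }
    data.frame(gene_id = rownames(profiles)[i], class = cls,
               preferred_tissue = pref, score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Thin, checked wrapper used for all co-expression computations. Constant
#' vectors raise an explicit undefined-correlation error rather than returning
#' NA or 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The PCC, in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("PCC requires at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("PCC undefined for a constant vector")
  stats::cor(x, y, method = "pearson")
}

#' Top-k co-expressed genes for a bait
#'
#' Ranks all other genes by PCC against the bait's sample profile and returns
#' the k best. Ties in PCC are broken by lexicographic gene id, making the
#' group deterministic.
#'
#' @param x An [expression_set()].
#' @param bait Gene id present in `x`.
#' @param k Number of co-expressed genes to return (`k < nrow - 1` allowed up
#'   to all non-bait genes).
#' @return data.frame with columns `gene_id` and `pcc`, PCC non-increasing;
#'   the bait itself is excluded.
#' @export
top_k_coexpressed <- function(x, bait, k) {
  stopifnot(inherits(x, "expr_set"))
  if (!bait %in% rownames(x$values)) stop("bait gene '", bait, "' not in matrix")
  if (k >= nrow(x$values)) stop("k must be smaller than the number of genes")
  bait_v <- x$values[bait, ]
  if (stats::sd(bait_v) == 0) stop("bait profile is constant; PCC undefined")
  others <- setdiff(rownames(x$values), bait)
  ok <- others[apply(x$values[others, , drop = FALSE], 1, stats::sd) > 0]
  pcc <- as.numeric(stats::cor(bait_v, t(x$values[ok, , drop = FALSE])))
  ord <- order(-pcc, ok)
  data.frame(gene_id = ok[ord][seq_len(k)], pcc = pcc[ord][seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Relative qPCR quantification (2^-dCt and 2^-ddCt)
#'
#' `relative_expression` converts a target/reference Ct pair into an
#' expression level relative to the reference gene, level = 2^-(Ct_target -
#' Ct_ref). `fold_change` compares two conditions, ratio = 2^-(dCt_treated -
#' dCt_control).
#'
#' @param ct_target,ct_ref Cycle-threshold values (> 0) for the target and
#'   reference gene.
#' @return Relative expression level (positive number).
#' @export
relative_expression <- function(ct_target, ct_ref) {
  stopifnot(ct_target > 0, ct_ref > 0)
  2^-(ct_target - ct_ref)
}

#' @rdname relative_expression
#' @param ct_target_treated,ct_ref_treated Ct pair for the treated condition.
#' @param ct_target_control,ct_ref_control Ct pair for the control condition.
#' @export
fold_change <- function(ct_target_treated, ct_ref_treated,
                        ct_target_control, ct_ref_control) {
  stopifnot(ct_target_treated > 0, ct_ref_treated > 0,
            ct_target_control > 0, ct_ref_control > 0)
  d_treated <- ct_target_treated - ct_ref_treated
  d_control <- ct_target_control - ct_ref_control
  2^-(d_treated - d_control)
}

#' Read / write expression matrices and tissue maps as TSV
#'
#' The expression TSV has a header row of sample ids and gene ids in the first
#' column (`gene_id`); the tissue map TSV has columns `sample_id`, `tissue`.
#'
#' @param path File path.
#' @param tissue_path Tissue map TSV path.
#' @return `read_expression_tsv`: an [expression_set()].
#' @export
read_expression_tsv <- function(path, tissue_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  tm <- utils::read.delim(tissue_path, stringsAsFactors = FALSE)
  expression_set(values, stats::setNames(tm$tissue, tm$sample_id))
}

#' @rdname read_expression_tsv
#' @param x An [expression_set()].
#' @export
write_expression_tsv <- function(x, path, tissue_path) {
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(x$tissue_map), tissue = unname(x$tissue_map)),
    tissue_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, tissue_path))
}

#' Export tissue profiles as TSV, optionally rendering a heat map
#'
#' The heat map (requires the pheatmap package) uses a fixed color scale,
#' default 5-15 log2 units to match array-compendium saturation bounds (use
#' 5-13 for compendia with a narrower dynamic range).
#'
#' @param profiles Genes x tissues matrix.
#' @param path TSV output path.
#' @param png_path Optional PNG path for the heat map.
#' @param scale_limits Color scale bounds, default `c(5, 15)`.
#' @return The TSV path, invisibly.
#' @export
write_tissue_profiles <- function(profiles, path, png_path = NULL,
                                  scale_limits = c(5, 15)) {
  tab <- data.frame(gene_id = rownames(profiles), profiles,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(png_path)) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stop("heat-map rendering requires the 'pheatmap' package")
    breaks <- seq(scale_limits[1], scale_limits[2], length.out = 101)
    pheatmap::pheatmap(profiles, cluster_cols = FALSE, breaks = breaks,
                       filename = png_path)
  }
  invisible(path)
}
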