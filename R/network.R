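#' Functional-class vocabulary for network nodes
#'
#' The fixed 11-class annotation vocabulary used for interaction-network
#' nodes (MapMan-bin-like labels).
#'
#' @return Character vector of the 11 class labels.
#' @export
network_classes <- function() {
  c("redox", "amino-acid metabolism",
    "cell cycle/lipid/photosynthesis/development",
    "DNA synthesis and repair", "protein degradation/PTM",
    "RNA/transcription", "signaling", "abiotic stress", "transport",
    "unknown", "other")
}

#' Build an annotated interaction network
#'
#' Constructs an undirected simple graph from a hub-partner edge table.
#' Self-edges are dropped with a warning; duplicate rows are collapsed into a
#' single edge with its multiplicity recorded. Node attributes: `class`
#' (validated against [network_classes()]), `known` (known-function flag) and
#' `is_hub`; node order is deterministic (hubs first, then partners by first
#' appearance).
#'
#' @param table data.frame with columns `hub`, `partner` and optionally
#'   `class` (partner's functional class) and `known` (logical).
#' @param hubs Character vector of hub ids (must appear in the table's `hub`
#'   column or as partners).
#' @return An [igraph::graph] with the attributes above (class
#'   `annotated_network` added).
#' @export
build_network <- function(table, hubs) {
  stopifnot(all(c("hub", "partner") %in% names(table)))
  if (!all(hubs %in% c(table$hub, table$partner)))
    stop("hub id absent from the edge table: ",
         paste(setdiff(hubs, c(table$hub, table$partner)), collapse = ", "))
  if ("class" %in% names(table)) {
    bad <- setdiff(stats::na.omit(unique(table$class)), network_classes())
    if (length(bad))
      stop("unknown functional class label(s): ", paste(bad, collapse = ", "),
           "; valid vocabulary: ", paste(network_classes(), collapse = " | "))
  }
  self <- table$hub == table$partner
  if (any(self)) {
    warning("dropping ", sum(self), " self-edge(s)")
    table <- table[!self, , drop = FALSE]
  }
  key <- paste(pmin(table$hub, table$partner), pmax(table$hub, table$partner),
               sep = "\r")
  mult <- table(key)[unique(key)]
  dedup <- table[!duplicated(key), , drop = FALSE]
  dedup$multiplicity <- as.integer(mult)

  nodes <- unique(c(hubs, dedup$hub, dedup$partner))
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  vert$is_hub <- vert$name %in% hubs
  cls <- rep(NA_character_, length(nodes)); names(cls) <- nodes
  knw <- rep(FALSE, length(nodes)); names(knw) <- nodes
  if ("class" %in% names(dedup)) cls[dedup$partner] <- dedup$class
  if ("known" %in% names(dedup)) knw[dedup$partner] <- as.logical(dedup$known)
  cls[hubs] <- "redox"   # hubs are family members of the redox class
  vert$class <- unname(cls)
  vert$known <- unname(knw)

  g <- igraph::graph_from_data_frame(
    dedup[, c("hub", "partner", "multiplicity")],
    directed = FALSE, vertices = vert)
  class(g) <- c("annotated_network", class(g))
  g
}

#' Overlay co-expression PCC on network edges
#'
#' Annotates every edge with the Pearson correlation between its endpoints'
#' expression profiles. Edges with an endpoint absent from the expression
#' matrix (or with a constant profile) get `pcc = NA` and a missing
#' co-expression flag ("no data"), never FALSE. The `coexpressed` flag is
#' strict: PCC must exceed the threshold, so PCC exactly at the threshold is
#' not flagged.
#'
#' @param network Network from [build_network()].
#' @param expr An [expression_set()] covering (a subset of) the node ids.
#' @param threshold PCC threshold (default 0.5, strict `>`).
#' @return The network with edge attributes `pcc` and `coexpressed`.
#' @export
overlay_coexpression <- function(network, expr, threshold = 0.5) {
  stopifnot(inherits(expr, "expr_set"))
  ends <- igraph::ends(network, igraph::E(network))
  pcc <- rep(NA_real_, nrow(ends))
  for (e in seq_len(nrow(ends))) {
    a <- ends[e, 1]; b <- ends[e, 2]
    if (!a %in% rownames(expr$values) || !b %in% rownames(expr$values)) next
    va <- expr$values[a, ]; vb <- expr$values[b, ]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    pcc[e] <- pearson(va, vb)
  }
  igraph::E(network)$pcc <- pcc
  igraph::E(network)$coexpressed <- ifelse(is.na(pcc), NA, pcc > threshold)
  network
}

#' Per-hub degrees and distinct-partner union
#'
#' Degrees count distinct partners (duplicate table rows were collapsed at
#' build time); the union counts each partner once even when shared between
#' hubs. The union equals the degree sum iff the partner sets are disjoint.
#'
#' @param network Network from [build_network()].
#' @return List: `degrees` (named integer per hub), `union_partners`
#'   (distinct-partner count across hubs), `n_interactions` (total edge
#'   multiplicity incident to hubs, i.e. raw interaction rows).
#' @export
hub_summary <- function(network) {
  hubs <- igraph::V(network)$name[igraph::V(network)$is_hub]
  if (!length(hubs)) stop("network has no hub nodes")
  partners <- lapply(hubs, function(h)
    setdiff(igraph::neighbors(network, h)$name, hubs))
  names(partners) <- hubs
  degrees <- vapply(partners, length, integer(1))
  inc <- unlist(igraph::incident_edges(network, hubs))
  n_inter <- sum(igraph::E(network)$multiplicity[unique(inc)])
  list(degrees = degrees,
       union_partners = length(unique(unlist(partners))),
       n_interactions = n_inter)
}

#' Export a network as SIF, GraphML or node/edge attribute TSVs
#'
#' SIF uses interaction type `pp` (one line per edge). GraphML (via igraph)
#' carries all node and edge attributes and round-trips losslessly through
#' [read_network_graphml()]. The TSV pair writes node attributes and edge
#' attributes; missing PCC values are serialized as the explicit token `NA`,
#' never as 0.
#'
#' @param network Network from [build_network()].
#' @param path Output file (for `"tsv"`, the node file; the edge file gets
#'   suffix `_edges.tsv`).
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  ends <- igraph::ends(network, igraph::E(network))
  if (format == "sif") {
    writeLines(paste(ends[, 1], "pp", ends[, 2]), path)
  } else if (format == "graphml") {
    # logical NA does not survive GraphML; ship the flag as numeric (NA ->
    # NaN) and restore it in read_network_graphml()
    g <- network
    if ("coexpressed" %in% igraph::edge_attr_names(g))
      igraph::E(g)$coexpressed <- as.numeric(igraph::E(g)$coexpressed)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    v <- igraph::V(network)
    nodes <- data.frame(id = v$name, class = v$class, known = v$known,
                        is_hub = v$is_hub, stringsAsFactors = FALSE)
    edge_attrs <- igraph::edge_attr(network)
    edges <- data.frame(from = ends[, 1], to = ends[, 2],
                        stringsAsFactors = FALSE)
    for (a in names(edge_attrs)) edges[[a]] <- edge_attrs[[a]]
    utils::write.table(nodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(edges, sub("\\.tsv$", "_edges.tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Re-import a GraphML network written by [export_network()]
#'
#' Restores NA edge PCCs (GraphML serializes them as NaN) and the
#' `annotated_network` class.
#'
#' @param path GraphML file.
#' @return An `annotated_network` igraph object.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("pcc" %in% igraph::edge_attr_names(g)) {
    pcc <- igraph::E(g)$pcc
    pcc[is.nan(pcc)] <- NA_real_
    igraph::E(g)$pcc <- pcc
    cox <- igraph::E(g)$coexpressed
    if (is.numeric(cox)) {
      cox[is.nan(cox)] <- NA
      igraph::E(g)$coexpressed <- as.logical(cox)
    }
  }
  class(g) <- c("annotated_network", class(g))
  g
}

#' Read an interaction edge TSV (columns: hub, partner\[, class, known\])
#'
#' @param path File path.
#' @return data.frame ready for [build_network()].
#' @export
read_interaction_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("hub", "partner") %in% names(tab)))
    stop("interaction TSV must have columns 'hub' and 'partner'")
  if ("known" %in% names(tab)) tab$known <- as.logical(tab$known)
  tab
}
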