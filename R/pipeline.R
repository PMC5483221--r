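#' Run the full comparative gene-family workflow
#'
#' End-to-end orchestration on synthetic or user-supplied inputs, mirroring
#' the analysis order of a comparative family study: meta-expression
#' aggregation and pattern classification, PCC co-expression groups around the
#' two baits, promoter scanning and incidence, group-common / group-unique CRE
#' comparison, NJ phylogeny with bootstrap supports and subgroup assignment,
#' and the interaction network with co-expression overlay. Every output lands
#' under `out_dir` with fixed names, and a JSON run manifest records the
#' configuration and the MD5 checksum of each output, so identical
#' config + seed reproduce identical checksums.
#'
#' @param config A [synth_config()] (used in demo mode to generate every
#'   input with known truth).
#' @param out_dir Output directory (created if absent).
#' @param inputs Optional list of pre-built inputs (`expr`, `promoters`,
#'   `groups`, `library`, `alignment`, `exemplars`, `interactions`,
#'   `network_expr`); any element left NULL is generated from `config`.
#' @param k_coexpr Co-expression group sizes for baits A and B (default
#'   `c(4, 5)`: group sizes minus the bait).
#' @param delta,floor Classification parameters for [classify_pattern()].
#' @param pcc_threshold Network co-expression threshold (default 0.5).
#' @param bootstrap_replicates Bootstrap replicates for the phylogeny
#'   (default 500).
#' @param quiet Suppress per-stage log lines (default FALSE).
#' @return Invisibly, a list with the in-memory stage results (`expr_truth`,
#'   `classes`, `coexpr`, `incidence`, `comparison`, `phylo`, `network`,
#'   `manifest`) and `paths` of all written files.
#' @export
run_workflow <- function(config = synth_config(), out_dir = "crefam_run",
                         inputs = list(), k_coexpr = NULL,
                         delta = 2.0, floor = 6.0, pcc_threshold = 0.5,
                         bootstrap_replicates = 500L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[crefam] ", ...)
  paths <- list()
  out <- function(name) file.path(out_dir, name)

  # ---- stage: inputs (generate whatever was not supplied) -----------------
  say("stage generate: seed ", config$seed)
  gen_expr <- if (is.null(inputs$expr)) gen_expression_compendium(config) else NULL
  expr <- if (is.null(gen_expr)) inputs$expr else gen_expr$expr
  prom <- if (is.null(inputs$promoters))
    gen_promoter_set(config, library = inputs$library) else
    list(promoters = inputs$promoters, groups = inputs$groups,
         library = inputs$library, truth = NULL)
  fam <- if (is.null(inputs$alignment)) gen_protein_family(config) else NULL
  alignment <- if (is.null(fam)) inputs$alignment else fam$alignment
  inter <- if (is.null(inputs$interactions)) gen_interaction_table(config) else
    inputs$interactions
  net_expr <- if (is.null(inputs$network_expr))
    gen_network_expression(config, inter)$expr else inputs$network_expr

  paths$expression <- out("expression.tsv")
  paths$tissue_map <- out("tissue_map.tsv")
  write_expression_tsv(expr, paths$expression, paths$tissue_map)
  paths$promoters_fasta <- out("promoters.fa")
  paths$promoters_bed <- out("promoters.bed")
  write_promoter_set(prom$promoters, paths$promoters_fasta, paths$promoters_bed)
  paths$motif_library <- out("motif_library.tsv")
  write_motif_library(prom$library, paths$motif_library)
  paths$interactions <- out("interactions.tsv")
  write_interaction_tsv(inter, paths$interactions)
  if (!is.null(prom$truth)) {
    paths$truth <- out("truth.json")
    jsonlite::write_json(
      list(motif_groups = prom$truth$motif_groups,
           planted_positions = prom$truth$positions,
           coexpression_blocks = if (!is.null(gen_expr))
             split(gen_expr$truth$gene_id[!is.na(gen_expr$truth$block)],
                   gen_expr$truth$block[!is.na(gen_expr$truth$block)]) else NULL,
           true_tree = if (!is.null(fam)) ape::write.tree(fam$true_tree) else NULL,
           hub_partners = inter$truth$partners),
      paths$truth, auto_unbox = TRUE, pretty = TRUE)
  }

  # ---- stage: expression --------------------------------------------------
  profiles <- aggregate_tissue_means(expr)
  classes <- classify_pattern(profiles, delta = delta, floor = floor)
  say("stage expression: ", nrow(profiles), " genes x ",
      ncol(profiles), " tissues")
  paths$tissue_profiles <- out("tissue_profiles.tsv")
  write_tissue_profiles(profiles, paths$tissue_profiles)
  paths$classes <- out("expression_classes.tsv")
  utils::write.table(classes, paths$classes, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ---- stage: co-expression ----------------------------------------------
  baits <- if (!is.null(gen_expr)) gen_expr$baits else
    stats::setNames(c(prom$groups$A[1], prom$groups$B[1]), c("A", "B"))
  if (is.null(k_coexpr))
    k_coexpr <- c(A = config$group_sizes[1] - 1L, B = config$group_sizes[2] - 1L)
  coexpr <- list(
    A = top_k_coexpressed(expr, baits[["A"]], k_coexpr[[1]]),
    B = top_k_coexpressed(expr, baits[["B"]], k_coexpr[[2]]))
  say("stage coexpr: baits ", paste(baits, collapse = ", "))
  paths$coexpr <- out("coexpression_groups.tsv")
  utils::write.table(
    rbind(cbind(group = "A", bait = baits[["A"]], coexpr$A),
          cbind(group = "B", bait = baits[["B"]], coexpr$B)),
    paths$coexpr, sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage: scan + compare ---------------------------------------------
  incidence <- build_incidence(prom$promoters, prom$library)
  say("stage scan: ", nrow(incidence), " motifs x ", ncol(incidence),
      " promoters, ", sum(incidence), " hits")
  paths$incidence <- out("incidence.tsv")
  utils::write.table(
    data.frame(motif = rownames(incidence), incidence, check.names = FALSE),
    paths$incidence, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- scan_promoters(prom$promoters, prom$library)
  paths$hits_gff3 <- out("motif_hits.gff3")
  write_hits_gff3(hits, paths$hits_gff3)

  common_a <- group_common(incidence, prom$groups$A)
  common_b <- group_common(incidence, prom$groups$B)
  comparison <- compare_groups(common_a, common_b)
  say("stage compare: |common A| ", length(common_a), ", |common B| ",
      length(common_b), ", unique A ", length(comparison$unique_a),
      ", unique B ", length(comparison$unique_b))
  paths$cre_report <- out("cre_comparison.tsv")
  paths$cre_summary <- out("cre_comparison.json")
  write_cre_report(comparison, incidence, prom$groups$A, prom$groups$B,
                   paths$cre_report, paths$cre_summary)

  # ---- stage: phylogeny ---------------------------------------------------
  dist <- p_distance_matrix(alignment)
  bs <- bootstrap_support(alignment, replicates = bootstrap_replicates,
                          seed = config$seed + 6L)
  exemplars <- if (!is.null(inputs$exemplars)) inputs$exemplars else if (!is.null(fam)) {
    firsts <- !duplicated(fam$subgroups)
    stats::setNames(unname(fam$subgroups[firsts]), names(fam$subgroups)[firsts])
  } else stop("exemplars required when a pre-built alignment is supplied")
  subgroups <- assign_subgroups(bs$tree, exemplars)
  say("stage phylo: ", length(bs$tree$tip.label), " taxa, ",
      bootstrap_replicates, " bootstrap replicates")
  paths$distances <- out("p_distances.tsv")
  write_distance_tsv(dist, paths$distances)
  paths$tree <- out("nj_tree.nwk")
  write_supported_tree(bs, paths$tree)
  paths$subgroups <- out("subgroups.tsv")
  utils::write.table(subgroups$assignment, paths$subgroups, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # ---- stage: network -----------------------------------------------------
  network <- build_network(inter$table, inter$hubs)
  network <- overlay_coexpression(network, net_expr, threshold = pcc_threshold)
  hubs_sum <- hub_summary(network)
  say("stage network: ", igraph::vcount(network), " nodes, ",
      igraph::ecount(network), " edges, partner union ",
      hubs_sum$union_partners)
  paths$network_sif <- out("network.sif")
  export_network(network, paths$network_sif, "sif")
  paths$network_graphml <- out("network.graphml")
  export_network(network, paths$network_graphml, "graphml")
  paths$network_nodes <- out("network_nodes.tsv")
  export_network(network, paths$network_nodes, "tsv")

  # ---- manifest -----------------------------------------------------------
  files <- unlist(paths)
  manifest <- list(
    tool = "crefam",
    version = as.character(utils::packageVersion("crefam")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    parameters = list(k_coexpr = as.list(k_coexpr), delta = delta,
                      floor = floor, pcc_threshold = pcc_threshold,
                      bootstrap_replicates = bootstrap_replicates),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  paths$manifest <- out("manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  say("run complete: ", length(files) + 1L, " files in ", out_dir)

  invisible(list(expr = expr, expr_truth = gen_expr$truth, baits = baits,
                 classes = classes, coexpr = coexpr, incidence = incidence,
                 comparison = comparison,
                 phylo = list(distances = dist, bootstrap = bs,
                              subgroups = subgroups,
                              truth = if (!is.null(fam)) fam else NULL),
                 network = list(graph = network, summary = hubs_sum),
                 promoter_truth = prom$truth, manifest = manifest,
                 paths = paths))
}
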