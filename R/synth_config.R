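#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generator: a tissue-structured
#' expression compendium with planted co-expression blocks, promoter sets with
#' planted group-specific motifs over an i.i.d. background, a protein family
#' evolved on a known 4-subgroup tree, and a hub-structured interaction table.
#' Defaults emulate the study conditions of a rice gene-family analysis: six
#' tissues (leaf, shoot, root, flower, pollen, seed), log2 intensities bounded
#' in \[5, 15\] mimicking array saturation, 2-kb promoters, and promoter groups
#' of five and six genes around two tandem-duplicate baits.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @param n_genes Number of genes in the expression compendium.
#' @param tissues Character vector of tissue labels (>= 2).
#' @param reps_per_tissue Samples per tissue (>= 1).
#' @param intensity_floor,intensity_ceiling Log2 clipping bounds emulating
#'   array saturation (defaults 5 and 15).
#' @param effect_size Log2 boost of a tissue-preferential gene in its
#'   preferred tissue (default 4).
#' @param tissue_profile_sd Per-tissue log2 jitter of a preferential gene's
#'   profile around its baseline (default 0.75). Members of a planted
#'   co-expression block share one realized jitter vector, giving the block a
#'   distinctive multi-tissue signature; independent preferential genes draw
#'   their own. Forced to 0 when `effect_size` is 0 (no planted structure).
#' @param condition_sd SD of the per-sample condition response of a
#'   preferential gene (default 1). Arrays of a compendium are heterogeneous
#'   beyond tissue of origin; co-regulated genes respond to that heterogeneity
#'   together. Block members share one realized condition-response vector,
#'   independent preferential genes draw their own, ubiquitous and suppressed
#'   genes have none. Forced to 0 when `effect_size` is 0.
#' @param noise_sd Per-sample log2 noise SD (default 0.5).
#' @param promoter_length Upstream promoter length in bp (default 2000).
#' @param extra_length Length of the optional first-intron/exon segment
#'   appended after the ATG (default 0 = upstream only).
#' @param gc_content Background GC fraction in (0, 1), default 0.44 (typical
#'   of rice promoter regions).
#' @param group_sizes Sizes of the two promoter groups (default `c(5, 6)`).
#' @param planted_motifs_per_group Number of motifs planted in every promoter
#'   of each group (default 3).
#' @param n_decoy_motifs Decoy motifs appended to the default library
#'   (default 10).
#' @param hub_degrees Degrees of the interaction hubs (default
#'   `c(60, 16, 3, 3)`).
#' @param coexpressed_per_hub Number of partners per hub whose expression
#'   profiles are generated to exceed PCC 0.5 with the hub (default
#'   `c(12, 3, 2, 0)`).
#' @param protein_clades Number of subgroup clades in the protein family
#'   (>= 4 by default usage; default 4).
#' @param taxa_per_clade Taxa per clade (default 5).
#' @param protein_length Alignment length in residues (default 200).
#' @param within_clade_branch Expected substitutions/site on within-clade
#'   branches (default 0.05).
#' @param stem_branch Expected substitutions/site on each clade stem
#'   (default 0.4).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 200L,
                         tissues = c("leaf", "shoot", "root", "flower",
                                     "pollen", "seed"),
                         reps_per_tissue = 6L,
                         intensity_floor = 5,
                         intensity_ceiling = 15,
                         effect_size = 4,
                         tissue_profile_sd = 0.75,
                         condition_sd = 1,
                         noise_sd = 0.5,
                         promoter_length = 2000L,
                         extra_length = 0L,
                         gc_content = 0.44,
                         group_sizes = c(5L, 6L),
                         planted_motifs_per_group = 3L,
                         n_decoy_motifs = 10L,
                         hub_degrees = c(60L, 16L, 3L, 3L),
                         coexpressed_per_hub = c(12L, 3L, 2L, 0L),
                         protein_clades = 4L,
                         taxa_per_clade = 5L,
                         protein_length = 200L,
                         within_clade_branch = 0.05,
                         stem_branch = 0.4) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              tissues = as.character(tissues),
              reps_per_tissue = as.integer(reps_per_tissue),
              intensity_floor = intensity_floor,
              intensity_ceiling = intensity_ceiling,
              effect_size = effect_size,
              tissue_profile_sd = tissue_profile_sd,
              condition_sd = condition_sd, noise_sd = noise_sd,
              promoter_length = as.integer(promoter_length),
              extra_length = as.integer(extra_length),
              gc_content = gc_content,
              group_sizes = as.integer(group_sizes),
              planted_motifs_per_group = as.integer(planted_motifs_per_group),
              n_decoy_motifs = as.integer(n_decoy_motifs),
              hub_degrees = as.integer(hub_degrees),
              coexpressed_per_hub = as.integer(coexpressed_per_hub),
              protein_clades = as.integer(protein_clades),
              taxa_per_clade = as.integer(taxa_per_clade),
              protein_length = as.integer(protein_length),
              within_clade_branch = within_clade_branch,
              stem_branch = stem_branch)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$intensity_floor >= cfg$intensity_ceiling)
    stop("intensity_floor must be below intensity_ceiling")
  if (cfg$reps_per_tissue < 1L)
    stop("reps_per_tissue must be a positive count")
  if (length(cfg$tissues) < 2L) stop("need at least 2 tissues")
  if (cfg$n_genes < sum(cfg$group_sizes))
    stop("n_genes must accommodate the two co-expression blocks")
  if (any(cfg$group_sizes < 1L)) stop("group sizes must be >= 1")
  if (cfg$gc_content < 0 || cfg$gc_content > 1)
    stop("gc_content must be a fraction in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(cfg$coexpressed_per_hub) != length(cfg$hub_degrees))
    stop("coexpressed_per_hub must align with hub_degrees")
  if (any(cfg$coexpressed_per_hub > cfg$hub_degrees))
    stop("coexpressed_per_hub cannot exceed hub degree")
  invisible(cfg)
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_synth_config`: a `synth_config` object.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @param config A `synth_config` object.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
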