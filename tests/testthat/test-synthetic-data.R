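test_that("generator configuration is validated", {
  expect_error(synth_config(reps_per_tissue = 0), "positive count")
  expect_error(synth_config(intensity_floor = 15, intensity_ceiling = 5), "below")
  expect_error(synth_config(gc_content = 1.2), "fraction")
  expect_error(synth_config(n_genes = 5), "accommodate")
})

test_that("expression compendium is deterministic and respects clipping", {
  cfg <- synth_config(seed = 9, n_genes = 40L)
  a <- gen_expression_compendium(cfg)
  b <- gen_expression_compendium(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  # byte-identical TSV output
  fa <- tempfile(); fb <- tempfile(); ta <- tempfile(); tb <- tempfile()
  write_expression_tsv(a$expr, fa, ta); write_expression_tsv(b$expr, fb, tb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  expect_true(all(a$expr$values >= cfg$intensity_floor))
  expect_true(all(a$expr$values <= cfg$intensity_ceiling))
})

test_that("zero noise makes block members perfectly correlated", {
  cfg <- synth_config(seed = 2, n_genes = 20L, noise_sd = 0)
  ge <- gen_expression_compendium(cfg)
  blockA <- ge$truth$gene_id[!is.na(ge$truth$block) & ge$truth$block == "A"]
  combos <- utils::combn(blockA, 2)
  for (k in seq_len(ncol(combos)))
    expect_equal(pearson(ge$expr$values[combos[1, k], ],
                         ge$expr$values[combos[2, k], ]), 1.0)
})

test_that("no planted effect means every expressed gene is ubiquitous", {
  cfg <- synth_config(seed = 6, n_genes = 50L, effect_size = 0)
  ge <- gen_expression_compendium(cfg)
  calls <- classify_pattern(aggregate_tissue_means(ge$expr))
  expressed <- calls$class != "suppressed"
  expect_true(all(calls$class[expressed] == "ubiquitous"))
})

test_that("motif library ships the 13 elements plus validated decoys", {
  lib <- gen_motif_library(0)
  expect_equal(nrow(lib), 13L)
  expect_true(any(lib$name == "ABREOSRAB21" & lib$consensus == "ACGTSSSC"))
  expect_true(any(lib$name == "TATCCAYMOTIFOSRAMY3D" & lib$consensus == "TATCCAY"))
  expect_true(any(lib$name == "PBOX1" & lib$consensus == "TGRAAG"))
  lib2 <- gen_motif_library(15, seed = 3)
  expect_equal(nrow(lib2), 28L)
  for (cons in lib2$consensus) expect_silent(validate_consensus(cons))
  expect_false(anyDuplicated(lib2$consensus) > 0)
  expect_identical(gen_motif_library(5, seed = 8), gen_motif_library(5, seed = 8))
})

test_that("promoter planting is sound and cross-group pure", {
  cfg <- synth_config(seed = 12, promoter_length = 1000L, n_decoy_motifs = 4L)
  ps <- gen_promoter_set(cfg)
  expect_equal(Biostrings::width(ps$promoters$sequences),
               rep(1000L, sum(cfg$group_sizes)))
  hits <- scan_promoters(ps$promoters, ps$library)
  # every recorded planted position is recovered by scanning
  p <- ps$truth$positions
  for (r in seq_len(nrow(p)))
    expect_true(any(hits$gene_id == p$gene_id[r] & hits$motif == p$motif[r] &
                    hits$start == p$start[r] & hits$strand == "+"))
  # planted motifs occur in every promoter of their group, never across
  inc <- build_incidence(ps$promoters, ps$library)
  mg <- ps$truth$motif_groups
  for (r in seq_len(nrow(mg))) {
    own <- ps$groups[[mg$group[r]]]
    other <- ps$groups[[setdiff(c("A", "B"), mg$group[r])]]
    expect_true(all(inc[mg$motif[r], own] >= 1L))
    expect_true(all(inc[mg$motif[r], other] == 0L))
  }
  # determinism
  ps2 <- gen_promoter_set(cfg)
  expect_identical(as.character(ps$promoters$sequences),
                   as.character(ps2$promoters$sequences))
})

test_that("GC-free background contains only A/T and defeats S-motifs", {
  cfg <- synth_config(seed = 5, gc_content = 0, planted_motifs_per_group = 0L,
                      n_decoy_motifs = 0L, promoter_length = 500L)
  ps <- gen_promoter_set(cfg)
  freq <- Biostrings::alphabetFrequency(ps$promoters$sequences)
  expect_true(all(freq[, c("C", "G")] == 0))
  inc <- build_incidence(ps$promoters, ps$library)
  expect_true(all(inc["ABREOSRAB21", ] == 0L))   # ACGTSSSC cannot match
  expect_equal(nrow(ps$truth$positions), 0L)
})

test_that("overlong motifs are refused", {
  lib <- data.frame(name = "LONG", consensus = strrep("A", 600))
  expect_error(gen_promoter_set(synth_config(seed = 1, promoter_length = 500L),
                                library = lib),
               "longer than promoter")
})

test_that("protein family evolves on the recorded tree", {
  cfg <- synth_config(seed = 21)
  fam <- gen_protein_family(cfg)
  expect_equal(length(fam$alignment), cfg$protein_clades * cfg$taxa_per_clade)
  expect_true(all(Biostrings::width(fam$alignment) == cfg$protein_length))
  # same seed twice -> identical FASTA
  fam2 <- gen_protein_family(cfg)
  expect_identical(as.character(fam$alignment), as.character(fam2$alignment))
  # zero substitution rate -> identical sequences, all-zero distances
  frozen <- gen_protein_family(synth_config(seed = 3, within_clade_branch = 0,
                                            stem_branch = 0))
  expect_equal(length(unique(as.character(frozen$alignment))), 1L)
  d0 <- p_distance_matrix(frozen$alignment)
  expect_true(all(d0 == 0))
  # within-clade distances below between-clade distances
  d <- p_distance_matrix(fam$alignment)
  cl <- fam$subgroups[rownames(d)]
  same <- outer(cl, cl, "==") & upper.tri(d)
  diff <- outer(cl, cl, "!=") & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff]))
})

test_that("interaction tables have the configured hub structure", {
  cfg <- synth_config(seed = 31)
  it <- gen_interaction_table(cfg)
  expect_equal(nrow(it$table), sum(cfg$hub_degrees))
  expect_equal(unname(vapply(it$truth$partners, length, integer(1))),
               cfg$hub_degrees)
  # disjoint partner sets by default
  expect_equal(length(unique(it$table$partner)), sum(cfg$hub_degrees))
  expect_true(all(it$table$class %in% network_classes()))
  expect_equal(sum(!duplicated(it$table$partner) & it$table$known), 3L)
  # single-edge degenerate case
  it1 <- gen_interaction_table(synth_config(seed = 1, hub_degrees = 1L,
                                            coexpressed_per_hub = 0L))
  expect_equal(nrow(it1$table), 1L)
  expect_equal(length(unique(c(it1$table$hub, it1$table$partner))), 2L)
  # full overlap with equal degrees collapses the union to one partner set
  it_ov <- gen_interaction_table(synth_config(seed = 2, hub_degrees = c(5L, 5L),
                                              coexpressed_per_hub = c(0L, 0L)),
                                 overlap_fraction = 1)
  g <- build_network(it_ov$table, it_ov$hubs)
  expect_equal(hub_summary(g)$union_partners, 5L)
})
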