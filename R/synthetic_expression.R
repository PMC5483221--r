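#' Generate a tissue-structured expression compendium with planted truth
#'
#' Emulates a log2-normalized microarray compendium aggregated by tissue. Two
#' co-expression blocks are planted (sizes `group_sizes`, first member of each
#' is the bait): all members of a block share one tissue-mean profile —
#' flat baseline plus `effect_size` in the block's preferred tissue (block A:
#' `seed`, block B: `root`, falling back to the first two tissues when those
#' labels are absent) — and differ only by i.i.d. per-sample noise. Remaining
#' genes are an independent mix of ubiquitous, tissue-preferential (random
#' preferred tissue, boost `effect_size`) and suppressed (all tissue means
#' below 6) genes. All values are clipped to
#' \[`intensity_floor`, `intensity_ceiling`\], mimicking array saturation.
#'
#' @param config A [synth_config()].
#' @return List with elements:
#'   \describe{
#'     \item{expr}{an [expression_set()] of `n_genes` x
#'       (tissues x reps) samples}
#'     \item{truth}{data.frame `gene_id`, `class`, `preferred_tissue`,
#'       `block` (`"A"`, `"B"` or NA)}
#'     \item{baits}{named character vector, bait gene id per block}
#'   }
#' @export
gen_expression_compendium <- function(config = synth_config()) {
  validate_synth_config(config)
  set.seed(config$seed)
  nt <- length(config$tissues)
  n_samples <- nt * config$reps_per_tissue
  sample_tissue <- rep(config$tissues, each = config$reps_per_tissue)
  sample_ids <- paste0(sample_tissue, "_r", rep(seq_len(config$reps_per_tissue), nt))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  pref_a <- if ("seed" %in% config$tissues) "seed" else config$tissues[1]
  pref_b <- if ("root" %in% config$tissues) "root" else config$tissues[2]

  n_a <- config$group_sizes[1]; n_b <- config$group_sizes[2]
  block <- rep(NA_character_, config$n_genes)
  block[seq_len(n_a)] <- "A"
  block[n_a + seq_len(n_b)] <- "B"

  truth_class <- character(config$n_genes)
  truth_pref <- rep(NA_character_, config$n_genes)

  # Tissue-mean profile of a preferential gene: baseline + per-tissue jitter
  # (the gene's multi-tissue signature) + effect boost in the preferred
  # tissue. Block members share one realized profile, so a block is marked by
  # its signature, not just by the boosted tissue. No jitter when there is no
  # planted effect.
  jitter_sd <- if (config$effect_size > 0) config$tissue_profile_sd else 0
  cond_sd <- if (config$effect_size > 0) config$condition_sd else 0
  profile_for <- function(pref) {
    base <- stats::runif(1, 7, 10)
    p <- base + stats::rnorm(nt, sd = jitter_sd)
    names(p) <- config$tissues
    p[pref] <- p[pref] + config$effect_size
    p
  }
  prof_a <- profile_for(pref_a)
  prof_b <- profile_for(pref_b)
  # shared per-sample condition response of each block (compendium arrays are
  # heterogeneous beyond tissue; co-regulated genes track that together)
  cond_a <- stats::rnorm(n_samples, sd = cond_sd)
  cond_b <- stats::rnorm(n_samples, sd = cond_sd)

  means <- matrix(0, config$n_genes, nt,
                  dimnames = list(gene_ids, config$tissues))
  cond <- matrix(0, config$n_genes, n_samples)
  for (i in seq_len(config$n_genes)) {
    if (identical(block[i], "A")) {
      means[i, ] <- prof_a
      cond[i, ] <- cond_a
      truth_class[i] <- if (config$effect_size > 0) "tissue-preferential" else "ubiquitous"
      truth_pref[i] <- if (config$effect_size > 0) names(which.max(prof_a)) else NA_character_
    } else if (identical(block[i], "B")) {
      means[i, ] <- prof_b
      cond[i, ] <- cond_b
      truth_class[i] <- if (config$effect_size > 0) "tissue-preferential" else "ubiquitous"
      truth_pref[i] <- if (config$effect_size > 0) names(which.max(prof_b)) else NA_character_
    } else {
      u <- stats::runif(1)
      if (u < 0.5) {                      # ubiquitous
        means[i, ] <- stats::runif(1, 7, 12)
        truth_class[i] <- "ubiquitous"
      } else if (u < 0.8) {               # tissue-preferential
        pref <- sample(config$tissues, 1)
        means[i, ] <- profile_for(pref)
        cond[i, ] <- stats::rnorm(n_samples, sd = cond_sd)
        truth_class[i] <- if (config$effect_size > 0) "tissue-preferential" else "ubiquitous"
        truth_pref[i] <- if (config$effect_size > 0)
          names(which.max(means[i, ])) else NA_character_
      } else {                            # suppressed: means below the 6.0 call floor
        means[i, ] <- stats::runif(1, config$intensity_floor,
                                   min(5.8, config$intensity_ceiling))
        truth_class[i] <- "suppressed"
      }
    }
  }

  values <- means[, sample_tissue, drop = FALSE] + cond +
    matrix(stats::rnorm(config$n_genes * n_samples, sd = config$noise_sd),
           config$n_genes, n_samples)
  values <- pmin(pmax(values, config$intensity_floor), config$intensity_ceiling)
  colnames(values) <- sample_ids

  expr <- expression_set(values, stats::setNames(sample_tissue, sample_ids))
  truth <- data.frame(gene_id = gene_ids, class = truth_class,
                      preferred_tissue = truth_pref, block = block,
                      stringsAsFactors = FALSE)
  baits <- c(A = gene_ids[1], B = gene_ids[n_a + 1L])
  list(expr = expr, truth = truth, baits = baits)
}
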