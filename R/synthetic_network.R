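#' Generate a hub-structured interaction table
#'
#' One hub per entry of `config$hub_degrees`, each with that many partners.
#' Partner sets are disjoint by default; `overlap_fraction` > 0 lets later
#' hubs re-use partners of earlier hubs (each partner slot of hub i >= 2 is an
#' already-used partner with that probability). Ids use a rice-locus-like
#' format; partner classes are drawn from the 11-class vocabulary
#' ([network_classes()]) and `n_known` partners carry the known-function flag.
#'
#' @param config A [synth_config()].
#' @param overlap_fraction Probability a partner slot re-uses an earlier
#'   hub's partner (default 0 = disjoint).
#' @param n_known Number of partners flagged as functionally characterized
#'   (default 3).
#' @return List: `table` (data.frame `hub`, `partner`, `class`, `known`),
#'   `hubs` (character vector) and `truth` (list with `partners`, the named
#'   list of true partner sets per hub).
#' @export
gen_interaction_table <- function(config = synth_config(),
                                  overlap_fraction = 0, n_known = 3L) {
  validate_synth_config(config)
  if (!length(config$hub_degrees)) stop("hub_degrees must be non-empty")
  set.seed(config$seed + 4L)
  n_hubs <- length(config$hub_degrees)
  total <- sum(config$hub_degrees)
  ids <- synth_locus_ids(n_hubs + total)
  hubs <- ids[seq_len(n_hubs)]
  pool <- ids[-seq_len(n_hubs)]

  partners <- list(); used <- character(0); next_free <- 1L
  for (i in seq_len(n_hubs)) {
    deg <- config$hub_degrees[i]
    mine <- character(0)
    for (s in seq_len(deg)) {
      reuse <- length(used) > 0 && stats::runif(1) < overlap_fraction
      cand <- if (reuse) sample(setdiff(used, mine), 1L) else {
        p <- pool[next_free]; next_free <- next_free + 1L; p
      }
      mine <- c(mine, cand)
    }
    partners[[hubs[i]]] <- mine
    used <- unique(c(used, mine))
  }

  table <- do.call(rbind, lapply(hubs, function(h)
    data.frame(hub = h, partner = partners[[h]], stringsAsFactors = FALSE)))
  all_partners <- unique(table$partner)
  cls <- stats::setNames(sample(network_classes(), length(all_partners),
                                replace = TRUE), all_partners)
  known <- stats::setNames(rep(FALSE, length(all_partners)), all_partners)
  known[sample(all_partners, min(n_known, length(all_partners)))] <- TRUE
  table$class <- unname(cls[table$partner])
  table$known <- unname(known[table$partner])
  rownames(table) <- NULL
  list(table = table, hubs = hubs, truth = list(partners = partners))
}

synth_locus_ids <- function(n) {
  ids <- character(0)
  while (length(ids) < n) {
    cand <- sprintf("LOC_Os%02dg%05d", sample(1:12, n, replace = TRUE),
                    sample(10000:79999, n, replace = TRUE))
    ids <- unique(c(ids, cand))
  }
  ids[seq_len(n)]
}

#' Generate expression profiles for network genes with controlled PCC
#'
#' Builds an [expression_set()] over the configured tissues x replicates for
#' every hub and partner, engineered so that exactly
#' `config$coexpressed_per_hub[i]` partners of hub i have PCC > 0.5 with it:
#' co-expressed partners are noisy copies of the hub profile (re-drawn until
#' PCC > 0.55), and all remaining partners are residualized against their
#' hub's centered profile, pinning their PCC at 0. Hubs receive
#' tissue-structured profiles (distinct preferred tissues).
#'
#' @param config A [synth_config()].
#' @param interactions Result of [gen_interaction_table()].
#' @return List: `expr` (an [expression_set()]) and `truth` (data.frame
#'   `hub`, `partner`, `coexpressed`).
#' @export
gen_network_expression <- function(config = synth_config(),
                                   interactions = gen_interaction_table(config)) {
  validate_synth_config(config)
  set.seed(config$seed + 5L)
  hubs <- interactions$hubs
  partners <- interactions$truth$partners
  nt <- length(config$tissues)
  n_rep <- config$reps_per_tissue
  n_samp <- nt * n_rep
  sample_tissue <- rep(config$tissues, each = n_rep)
  sample_ids <- paste0(sample_tissue, "_r", rep(seq_len(n_rep), nt))

  hub_profile <- function(i) {
    base <- stats::runif(1, 7, 9)
    means <- rep(base, nt)
    means[(i - 1L) %% nt + 1L] <- base + config$effect_size
    rep(means, each = n_rep) + stats::rnorm(n_samp, sd = config$noise_sd)
  }

  rows <- list(); truth <- list()
  for (i in seq_along(hubs)) {
    h <- hubs[i]
    hp <- hub_profile(i)
    rows[[h]] <- hp
    hc <- hp - mean(hp)
    k_co <- config$coexpressed_per_hub[i]
    mine <- partners[[h]]
    co_set <- if (k_co > 0) mine[seq_len(k_co)] else character(0)
    for (p in mine) {
      if (p %in% names(rows)) next   # shared partner: keep first profile
      if (p %in% co_set) {
        repeat {
          v <- hp + stats::rnorm(n_samp, sd = max(config$noise_sd, 0.3))
          if (pearson(hp, v) > 0.55) break
        }
      } else {
        z <- stats::rnorm(n_samp, mean = stats::runif(1, 7, 11), sd = 1)
        v <- z - hc * sum(z * hc) / sum(hc * hc)   # PCC with hub pinned at 0
      }
      rows[[p]] <- v
    }
    truth[[h]] <- data.frame(hub = h, partner = mine,
                             coexpressed = mine %in% co_set,
                             stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  values <- pmin(pmax(values, config$intensity_floor), config$intensity_ceiling)
  rownames(values) <- names(rows)
  colnames(values) <- sample_ids
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(expr = expression_set(values, stats::setNames(sample_tissue, sample_ids)),
       truth = truth)
}

#' Write an interaction table as TSV
#' @param interactions Result of [gen_interaction_table()] (or a bare
#'   data.frame).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_interaction_tsv <- function(interactions, path) {
  tab <- if (is.data.frame(interactions)) interactions else interactions$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
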