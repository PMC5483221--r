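#' Default cis-regulatory element library
#'
#' The 13 named IUPAC consensi used throughout the package as the default
#' motif library. Seven are seed/endosperm-associated elements (four
#' ABA-responsive ABRE variants, one GA-down element, and the TATCCA(Y)
#' alpha-amylase elements) and six are root/embryo-associated elements
#' (GA-responsive elements, an organ-specific root-nodule element, and two
#' WUSCHEL-type homeobox promoter elements).
#'
#' @return A data.frame with columns `name` and `consensus`.
#' @export
default_motif_library <- function() {
  data.frame(
    name = c("ABREDISTBBNNAPA", "ABREAZMRAB28", "ABREBZMRAB28", "ABREOSRAB21",
             "GADOWNAT", "TATCCAYMOTIFOSRAMY3D", "TATCCAOSAMY",
             "PBOX1", "GAREAT", "GARE1OSREP1", "OSE1ROOTNODULE",
             "LEAFYATAG", "WUSATAg"),
    consensus = c("GCCACTTGTC", "GCCACGTGGG", "TCCACGTCTC", "ACGTSSSC",
                  "ACGTGTC", "TATCCAY", "TATCCA",
                  "TGRAAG", "TAACAAR", "TAACAGA", "AAAGAT",
                  "CCAATGT", "TTAATGG"),
    stringsAsFactors = FALSE
  )
}

# Names of the seed/endosperm-associated vs root/embryo-associated halves of
# the default library; used by the promoter generator to pick biologically
# coherent planted sets.
seed_motif_names <- function() default_motif_library()$name[1:7]
root_motif_names <- function() default_motif_library()$name[8:13]

#' Generate a motif library: the 13 default elements plus random decoys
#'
#' Decoys are random IUPAC consensi of length 6-10. Each decoy position is a
#' concrete base with probability 0.8 and a two-fold degenerate code
#' (R/Y/S/W/K/M) otherwise, keeping decoy degeneracy comparable to real plant
#' promoter elements.
#'
#' @param n_decoys Number of decoy motifs to append (>= 0).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `name` and `consensus`; the first 13 rows
#'   are the default library, decoys are named `DECOY01`, `DECOY02`, ...
#' @export
gen_motif_library <- function(n_decoys = 0L, seed = 1L) {
  stopifnot(is.numeric(n_decoys), n_decoys >= 0)
  n_decoys <- as.integer(n_decoys)
  lib <- default_motif_library()
  if (n_decoys == 0L) return(lib)
  set.seed(as.integer(seed))
  two_fold <- c("R", "Y", "S", "W", "K", "M")
  existing <- lib$consensus
  decoys <- character(0)
  while (length(decoys) < n_decoys) {
    len <- sample(6:10, 1L)
    sym <- ifelse(stats::runif(len) < 0.8,
                  sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  sample(two_fold, len, replace = TRUE))
    cons <- paste0(sym, collapse = "")
    if (!cons %in% c(existing, decoys)) decoys <- c(decoys, cons)
  }
  rbind(lib, data.frame(name = sprintf("DECOY%02d", seq_len(n_decoys)),
                        consensus = decoys, stringsAsFactors = FALSE))
}

#' Read / write a motif library TSV (columns: name, consensus)
#'
#' @param path File path.
#' @return `read_motif_library`: data.frame with columns `name`, `consensus`.
#' @export
read_motif_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "consensus") %in% names(lib)))
    stop("motif library TSV must have columns 'name' and 'consensus'")
  invisible(lapply(lib$consensus, validate_consensus))
  lib[, c("name", "consensus")]
}

#' @rdname read_motif_library
#' @param library Motif library data.frame.
#' @export
write_motif_library <- function(library, path) {
  utils::write.table(library[, c("name", "consensus")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
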