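# Relative adaptiveness of each codon in highly expressed Escherichia coli
# genes, after Sharp & Li (1987), the reference set classical codon-usage
# software defaults to. Values typed from the literature; DNA spelling.
ECOLI_W_RAW <- c(
  TTT = 0.296, TTC = 1.000,
  TTA = 0.020, TTG = 0.020, CTT = 0.042, CTC = 0.037, CTA = 0.007, CTG = 1.000,
  ATT = 0.185, ATC = 1.000, ATA = 0.003,
  ATG = 1.000,
  GTT = 1.000, GTC = 0.066, GTA = 0.495, GTG = 0.221,
  TCT = 1.000, TCC = 0.744, TCA = 0.077, TCG = 0.017, AGT = 0.085, AGC = 0.410,
  CCT = 0.070, CCC = 0.012, CCA = 0.135, CCG = 1.000,
  ACT = 0.965, ACC = 1.000, ACA = 0.076, ACG = 0.099,
  GCT = 1.000, GCC = 0.122, GCA = 0.586, GCG = 0.424,
  TAT = 0.239, TAC = 1.000,
  CAT = 0.291, CAC = 1.000,
  CAA = 0.124, CAG = 1.000,
  AAT = 0.051, AAC = 1.000,
  AAA = 1.000, AAG = 0.253,
  GAT = 0.434, GAC = 1.000,
  GAA = 1.000, GAG = 0.259,
  TGT = 0.500, TGC = 1.000,
  TGG = 1.000,
  CGT = 1.000, CGC = 0.356, CGA = 0.004, CGG = 0.004, AGA = 0.004, AGG = 0.002,
  GGT = 1.000, GGC = 0.724, GGA = 0.010, GGG = 0.019
)

#' Default CAI reference weights
#'
#' Relative-adaptiveness weights derived from the classical Escherichia coli
#' highly-expressed-gene reference (Sharp & Li 1987), re-normalised within
#' the synonymous families of the active code so that each family maximum is
#' 1. Codons absent from the source table (e.g. TGA, a sense codon only
#' under the mitochondrial code) enter with the rare-codon floor 0.01, and
#' all weights are floored at 0.01 so CAI's geometric mean stays finite.
#'
#' Absolute CAI/CBI/Fop values depend entirely on this choice of reference;
#' supply your own weights to [cai()] / [usage_indices()] for a different
#' reference set.
#'
#' @param code A [genetic_code()].
#' @return Named numeric vector over the code's sense codons, in (0, 1].
#' @export
reference_weights <- function(code = genetic_code(2)) {
  w <- setNames(rep(0.01, length(code$sense_codons)), code$sense_codons)
  known <- intersect(names(ECOLI_W_RAW), code$sense_codons)
  w[known] <- ECOLI_W_RAW[known]
  for (fam in code$families) {
    w[fam] <- pmax(w[fam] / max(w[fam]), 0.01)
  }
  w
}

#' Default optimal-codon set for CBI/Fop
#'
#' The family-maximal codons of [reference_weights()]: one optimal codon per
#' synonymous family (families of size >= 2 only).
#'
#' @param code A [genetic_code()].
#' @return Character vector of codons.
#' @export
reference_optimal_codons <- function(code = genetic_code(2)) {
  w <- reference_weights(code)
  fams <- code$families[lengths(code$families) >= 2]
  vapply(fams, function(fam) fam[which.max(w[fam])], character(1),
         USE.NAMES = FALSE)
}
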