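#' @importFrom stats cor.test lm coef rgamma runif setNames sd
#' @importFrom utils write.table read.delim
NULL

BASES <- c("T", "C", "A", "G")

#' All 64 DNA codons
#'
#' Codons are ordered T, C, A, G by position, the conventional codon-table
#' order.
#'
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0
  )))
}

#' Construct a genetic code
#'
#' Builds a genetic-code object from an NCBI translation-table identifier.
#' Table 2 (vertebrate mitochondrial: stops TAA/TAG/AGA/AGG, ATA = Met,
#' TGA = Trp) is the default throughout the package; table 1 is the standard
#' code.
#'
#' @param table_id NCBI translation-table id (integer or string), e.g. 2.
#' @return An object of class `genetic_code` with elements `table_id`,
#'   `codon_to_aa` (named character vector over all 64 codons, `"*"` for
#'   stops), `families` (named list: amino acid -> synonymous codons),
#'   `stop_codons`, `sense_codons`.
#' @examples
#' code <- genetic_code(2)
#' code$codon_to_aa["ATA"]   # "M" under the vertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 2) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[all_codons()]  # fixed codon order
  stops <- names(map)[map == "*"]
  sense <- names(map)[map != "*"]
  fams <- split(sense, map[sense])
  structure(
    list(
      table_id = as.integer(table_id),
      codon_to_aa = map,
      families = fams,
      stop_codons = stops,
      sense_codons = sense
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  sizes <- table(lengths(x$families))
  cat("Genetic code (translation table ", x$table_id, ")\n", sep = "")
  cat("  sense codons: ", length(x$sense_codons),
      ", stops: ", paste(x$stop_codons, collapse = "/"), "\n", sep = "")
  cat("  family sizes: ",
      paste(sprintf("%s-fold x %d", names(sizes), sizes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Synonymous-family size of each codon
#'
#' @param code A `genetic_code`.
#' @return Named integer vector over sense codons: size of the synonymous
#'   family each codon belongs to.
#' @export
family_sizes <- function(code) {
  fs <- rep(lengths(code$families), lengths(code$families))
  names(fs) <- unlist(code$families, use.names = FALSE)
  fs[code$sense_codons]
}

# codons in families with >= 2 members ("synonymous codons" in the L_sym sense)
synonymous_codons <- function(code) {
  fs <- family_sizes(code)
  names(fs)[fs >= 2]
}

#' Convert codons between DNA and RNA spelling
#'
#' Published codon tables use RNA spelling (AUC); sequences use DNA (ATC).
#'
#' @param x Character vector of codons.
#' @return The same codons in the other alphabet.
#' @export
rna_codon <- function(x) chartr("Tt", "Uu", x)

#' @rdname rna_codon
#' @export
dna_codon <- function(x) chartr("Uu", "Tt", x)

# Kyte-Doolittle hydropathy values
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)
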