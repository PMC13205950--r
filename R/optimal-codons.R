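#' Stratify genes into putative expression groups by ENC
#'
#' Sorts genes by ENC and takes the extreme `fraction` at each end. By the
#' usual convention, the lowest-ENC genes (strongest bias) form the
#' putative high-expression group and the highest-ENC genes the
#' low-expression group; `invert = TRUE` swaps the orientation. Ties are
#' broken by gene id so the split is deterministic.
#'
#' @param profiles data.frame from [usage_indices()].
#' @param fraction Fraction of genes in each group, in (0, 0.5]
#'   (default 0.2). Group size is `max(1, round(fraction * n))`.
#' @param invert Treat high-ENC genes as the high-expression group.
#' @return Object of class `expression_strata`: list with `high_group`,
#'   `low_group` (gene ids) and `fraction`.
#' @export
stratify_by_enc <- function(profiles, fraction = 0.2, invert = FALSE) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  n <- nrow(profiles)
  g <- max(1L, as.integer(round(fraction * n)))
  if (2 * g > n) stop("groups would overlap: too few genes for fraction ",
                      fraction)
  ord <- order(profiles$ENC, profiles$gene)
  low_enc <- profiles$gene[ord][seq_len(g)]
  high_enc <- profiles$gene[ord][seq(n - g + 1, n)]
  structure(list(
    high_group = if (invert) high_enc else low_enc,
    low_group = if (invert) low_enc else high_enc,
    fraction = fraction
  ), class = "expression_strata")
}

#' @export
print.expression_strata <- function(x, ...) {
  cat("Expression strata (fraction ", x$fraction, "):\n", sep = "")
  cat("  high-expression:", paste(x$high_group, collapse = ", "), "\n")
  cat("  low-expression: ", paste(x$low_group, collapse = ", "), "\n")
  invisible(x)
}

#' Delta-RSCU table from expression strata
#'
#' Computes pooled RSCU over all genes, over the high-expression stratum
#' and over the low-expression stratum, and their per-codon difference
#' `delta = RSCU_high - RSCU_low`. Codons of families unobserved in a
#' stratum get RSCU 0 there.
#'
#' @param genes A filtered [gene_set()].
#' @param strata An [stratify_by_enc()] result (or a list with
#'   `high_group` / `low_group` gene ids).
#' @return data.frame of class `delta_rscu_table`: amino_acid, codon (DNA),
#'   rscu_all, rscu_high, rscu_low, delta.
#' @export
delta_rscu <- function(genes, strata) {
  stopifnot(inherits(genes, "gene_set"))
  code <- genes$code
  pick <- function(ids) {
    missing <- setdiff(ids, names(genes$genes))
    if (length(missing)) stop("unknown gene ids: ",
                              paste(missing, collapse = ", "))
    if (!length(ids)) stop("empty stratum")
    pool_counts(gene_set(genes$genes[ids], genes$species_id, code))
  }
  r_all <- rscu(pool_counts(genes), code, absent = "zero")
  r_hi <- rscu(pick(strata$high_group), code, absent = "zero")
  r_lo <- rscu(pick(strata$low_group), code, absent = "zero")
  cods <- code$sense_codons
  out <- data.frame(
    amino_acid = unname(code$codon_to_aa[cods]), codon = cods,
    rscu_all = unname(r_all[cods]), rscu_high = unname(r_hi[cods]),
    rscu_low = unname(r_lo[cods]),
    delta = unname(r_hi[cods] - r_lo[cods]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("delta_rscu_table", "data.frame")
  out
}

#' Classify high-frequency, high-expression and optimal codons
#'
#' High-frequency codons have pooled RSCU strictly above `rscu_threshold`;
#' high-expression codons have delta-RSCU strictly above `delta_threshold`;
#' optimal codons satisfy both.
#'
#' @param table A [delta_rscu()] result (or any data.frame with columns
#'   codon, rscu_all, delta).
#' @param rscu_threshold RSCU cutoff (default 1.0, strict).
#' @param delta_threshold Delta-RSCU cutoff (default 0.08, strict).
#' @return Object of class `optimal_codon_set`: list with codon vectors
#'   `high_frequency`, `high_expression`, `optimal`, the evidence `table`,
#'   the thresholds, and `third_position` (table of third-position bases
#'   per set).
#' @export
classify_codons <- function(table, rscu_threshold = 1.0,
                            delta_threshold = 0.08) {
  hf <- table$codon[table$rscu_all > rscu_threshold]
  he <- table$codon[table$delta > delta_threshold]
  opt <- intersect(hf, he)
  third <- function(set) table(factor(substr(set, 3, 3), levels = BASES))
  structure(list(
    high_frequency = hf, high_expression = he, optimal = opt,
    table = table, rscu_threshold = rscu_threshold,
    delta_threshold = delta_threshold,
    third_position = rbind(high_frequency = third(hf),
                           high_expression = third(he),
                           optimal = third(opt))
  ), class = "optimal_codon_set")
}

#' @export
print.optimal_codon_set <- function(x, ...) {
  cat("Codon classification (RSCU > ", x$rscu_threshold,
      ", deltaRSCU > ", x$delta_threshold, "):\n", sep = "")
  cat("  high-frequency (", length(x$high_frequency), "): ",
      paste(rna_codon(x$high_frequency), collapse = " "), "\n", sep = "")
  cat("  high-expression (", length(x$high_expression), ")\n", sep = "")
  cat("  optimal (", length(x$optimal), "): ",
      paste(rna_codon(x$optimal), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read or write a delta-RSCU table in the published layout
#'
#' The layout is one row per codon: amino_acid, codon (RNA spelling), rscu,
#' rscu_high, rscu_low, delta_rscu, with an optional leading species
#' column. `read_rscu_table` accepts that layout and returns a
#' `delta_rscu_table` (codons in DNA spelling) per species.
#'
#' @param table A [delta_rscu()] result.
#' @param path TSV path.
#' @param species Optional species label column to write.
#' @export
write_rscu_table <- function(table, path, species = NULL) {
  out <- data.frame(
    amino_acid = table$amino_acid, codon = rna_codon(table$codon),
    rscu = round(table$rscu_all, 4), rscu_high = round(table$rscu_high, 4),
    rscu_low = round(table$rscu_low, 4), delta_rscu = round(table$delta, 4),
    stringsAsFactors = FALSE
  )
  if (!is.null(species)) out <- cbind(species = species, out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rscu_table
#' @return A named list of `delta_rscu_table` data.frames, one per species
#'   (a single unnamed element when the file has no species column).
#' @export
read_rscu_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("amino_acid", "codon", "rscu", "rscu_high", "rscu_low",
            "delta_rscu")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  split_by <- if ("species" %in% names(df)) df$species else rep("", nrow(df))
  lapply(split(df, split_by), function(d) {
    out <- data.frame(
      amino_acid = d$amino_acid, codon = dna_codon(d$codon),
      rscu_all = d$rscu, rscu_high = d$rscu_high, rscu_low = d$rscu_low,
      delta = d$delta_rscu, stringsAsFactors = FALSE
    )
    class(out) <- c("delta_rscu_table", "data.frame")
    out
  })
}

#' The packaged two-species delta-RSCU reference table
#'
#' The published per-codon RSCU / RSCU-high / RSCU-low / delta-RSCU values
#' for the ten-gene mitochondrial sets of *Enicurus scouleri* and
#' *Enicurus schistaceus*, shipped as a plain-text fixture for regression
#' tests and replay analyses.
#'
#' @return Named list of two `delta_rscu_table` data.frames
#'   (`E_scouleri`, `E_schistaceus`).
#' @export
enicurus_rscu_fixture <- function() {
  path <- system.file("extdata", "enicurus_rscu_table.tsv",
                      package = "mitocub", mustWork = TRUE)
  read_rscu_table(path)
}

#' Write an optimal-codon summary as TSV
#'
#' One row per optimal codon: amino acid, codon (RNA), pooled count, RSCU
#' and delta-RSCU.
#'
#' @param set A [classify_codons()] result.
#' @param counts Optional 64-slot pooled codon counts supplying the count
#'   column.
#' @param path Output TSV path.
#' @export
write_optimal_codons <- function(set, path, counts = NULL) {
  tab <- set$table
  idx <- match(set$optimal, tab$codon)
  out <- data.frame(
    amino_acid = tab$amino_acid[idx], codon = rna_codon(set$optimal),
    number = if (is.null(counts)) NA_integer_ else unname(counts[set$optimal]),
    rscu = round(tab$rscu_all[idx], 4),
    delta_rscu = round(tab$delta[idx], 4),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
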