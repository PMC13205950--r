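#' Correspondence analysis of a gene-by-codon RSCU matrix
#'
#' Classical correspondence analysis: the non-negative matrix is scaled to
#' a correspondence table, standardised residuals are formed and decomposed
#' by SVD, and principal coordinates are returned for rows (genes) and
#' columns (codons), with the fraction of total inertia carried by each
#' axis. Axis signs are canonicalised so the largest-magnitude row
#' coordinate on each axis is positive.
#'
#' @param mat Non-negative numeric matrix, genes in rows and codons in
#'   columns (e.g. from [rscu_matrix()]). All-zero rows/columns are dropped
#'   with a warning.
#' @return Object of class `coa_result`: list with `row_coords`,
#'   `col_coords` (principal coordinates, axes in columns), `inertia`
#'   (per-axis), `inertia_fraction`, `total_inertia`.
#' @export
coa <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("matrix must be non-negative")
  zr <- rowSums(mat) == 0
  zc <- colSums(mat) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ",
            sum(zc), " all-zero column(s)")
    mat <- mat[!zr, !zc, drop = FALSE]
  }
  n <- sum(mat)
  P <- mat / n
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(c_)) %*% diag(1 / sqrt(c_))
  sv <- svd(S)
  k <- min(nrow(mat), ncol(mat)) - 1
  sigma <- sv$d[seq_len(k)]
  sigma[sigma < 1e-12] <- 0
  inertia <- sigma^2
  total <- sum(inertia)
  # principal coordinates
  Fr <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(k), drop = FALSE] %*% diag(sigma, k)
  Gc <- diag(1 / sqrt(c_)) %*% sv$v[, seq_len(k), drop = FALSE] %*% diag(sigma, k)
  for (a in seq_len(k)) {
    if (sigma[a] == 0) next
    if (Fr[which.max(abs(Fr[, a])), a] < 0) {
      Fr[, a] <- -Fr[, a]
      Gc[, a] <- -Gc[, a]
    }
  }
  dimnames(Fr) <- list(rownames(mat), paste0("Axis", seq_len(k)))
  dimnames(Gc) <- list(colnames(mat), paste0("Axis", seq_len(k)))
  structure(list(
    row_coords = Fr, col_coords = Gc, inertia = inertia,
    inertia_fraction = if (total > 0) inertia / total else rep(0, k),
    total_inertia = total
  ), class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  k <- min(4, length(x$inertia))
  cat("Correspondence analysis: ", nrow(x$row_coords), " rows x ",
      nrow(x$col_coords), " columns, total inertia ",
      format(x$total_inertia, digits = 4), "\n", sep = "")
  if (k > 0) {
    cat("  inertia fractions (first ", k, " axes): ",
        paste(sprintf("%.2f%%", 100 * x$inertia_fraction[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Correlations between the first ordination axis and usage indices
#'
#' @param result A [coa()] result whose rows are the genes of `profiles`.
#' @param profiles data.frame from [usage_indices()].
#' @param fields Index columns to correlate against Axis 1.
#' @return data.frame: field, r, p, significance (`"*"` p < 0.05, `"**"`
#'   p < 0.01). Constant fields give NA.
#' @export
axis_correlations <- function(result, profiles,
                              fields = c("CAI", "CBI", "Fop", "ENC", "GC3s",
                                         "GC1", "GC2", "GC3", "GCall")) {
  stopifnot(inherits(result, "coa_result"))
  ax1 <- result$row_coords[, 1]
  idx <- match(rownames(result$row_coords), profiles$gene)
  if (anyNA(idx)) stop("row names of the ordination do not match gene ids")
  prof <- profiles[idx, , drop = FALSE]
  rows <- lapply(fields, function(f) {
    y <- prof[[f]]
    if (is.null(y)) stop("unknown field: ", f)
    if (sd(y) == 0 || sd(ax1) == 0) {
      return(data.frame(field = f, r = NA_real_, p = NA_real_,
                        significance = "", stringsAsFactors = FALSE))
    }
    ct <- cor.test(ax1, y)
    data.frame(field = f, r = unname(ct$estimate), p = ct$p.value,
               significance = if (ct$p.value < 0.01) "**"
                              else if (ct$p.value < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write correspondence-analysis results as TSV
#'
#' Writes three files under `prefix`: `<prefix>_gene_coords.tsv`,
#' `<prefix>_codon_coords.tsv` and `<prefix>_inertia.tsv`.
#'
#' @param result A [coa()] result.
#' @param prefix Output path prefix.
#' @export
write_coa <- function(result, prefix) {
  gc_df <- data.frame(gene = rownames(result$row_coords),
                      result$row_coords, check.names = FALSE)
  cc_df <- data.frame(codon = rownames(result$col_coords),
                      result$col_coords, check.names = FALSE)
  in_df <- data.frame(axis = seq_along(result$inertia),
                      inertia = result$inertia,
                      fraction = result$inertia_fraction)
  write.table(gc_df, paste0(prefix, "_gene_coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cc_df, paste0(prefix, "_codon_coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(in_df, paste0(prefix, "_inertia.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Gene-by-codon RSCU matrix for one species
#'
#' One row per gene, RSCU computed per gene; columns restricted to a codon
#' subset (see [codon_subset()]). Unobserved families give 0.
#'
#' @param genes A filtered [gene_set()].
#' @param subset Codon subset preset name or explicit codon vector (DNA or
#'   RNA spelling).
#' @return Numeric matrix, genes x codons.
#' @export
rscu_matrix <- function(genes, subset = "codonw59") {
  stopifnot(inherits(genes, "gene_set"))
  cols <- codon_subset(subset, genes$code)
  rows <- t(vapply(genes$genes, function(s) {
    v <- rscu(count_codons(s, genes$code), genes$code, absent = "zero")
    out <- setNames(rep(0, length(cols)), cols)
    common <- intersect(cols, names(v))
    out[common] <- v[common]  # subset codons outside the code's sense set stay 0
    out
  }, numeric(length(cols))))
  colnames(rows) <- cols
  rows
}
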