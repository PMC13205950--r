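#' Codon subsets for RSCU matrices
#'
#' Two presets are provided. `"codonw59"` is the 59-codon convention of
#' classical codon-usage software: all 64 codons minus the three standard
#' terminators (TAA, TAG, TGA) and the two standard-code single-codon
#' families (ATG, TGG) — the subset multi-species RSCU clustering studies
#' typically feed to their clustering tool. `"mito60"` is the vertebrate
#' mitochondrial sense set: 64 minus the four table-2 stops (TAA, TAG,
#' AGA, AGG). An explicit codon vector (DNA or RNA spelling) is passed
#' through after validation.
#'
#' @param subset `"codonw59"`, `"mito60"`, or a character vector of codons.
#' @param code A [genetic_code()] (used by `"mito60"`).
#' @return Character vector of DNA codons.
#' @export
codon_subset <- function(subset = "codonw59", code = genetic_code(2)) {
  if (length(subset) == 1 && subset %in% c("codonw59", "mito60")) {
    if (subset == "codonw59") {
      setdiff(all_codons(), c("TAA", "TAG", "TGA", "ATG", "TGG"))
    } else {
      setdiff(all_codons(), code$stop_codons)
    }
  } else {
    cods <- toupper(dna_codon(subset))
    bad <- setdiff(cods, all_codons())
    if (length(bad)) stop("not codons: ", paste(bad, collapse = ", "))
    if (anyDuplicated(cods)) stop("duplicate codons in subset")
    cods
  }
}

#' Species-by-codon pooled RSCU matrix
#'
#' Pools codon counts within each species' gene set, computes RSCU on the
#' pooled counts, and assembles one row per species over a codon subset.
#' Unobserved families give RSCU 0 with a warning.
#'
#' @param genesets List of filtered [gene_set()] objects (one per species,
#'   unique `species_id`s, sharing one genetic code).
#' @param subset Codon subset preset or explicit list (see
#'   [codon_subset()]).
#' @return Numeric matrix, species x codons.
#' @export
species_rscu_matrix <- function(genesets, subset = "codonw59") {
  stopifnot(length(genesets) >= 1)
  ids <- vapply(genesets, function(g) g$species_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  code <- genesets[[1]]$code
  cols <- codon_subset(subset, code)
  mat <- t(vapply(genesets, function(g) {
    counts <- pool_counts(g)
    if (sum(counts[code$sense_codons]) == 0) {
      stop("species '", g$species_id, "' has zero counted codons")
    }
    v <- rscu(counts, code, absent = "na")
    # subset codons outside the code's sense set (e.g. AGA/AGG under the
    # mitochondrial code) are structurally 0, not "unobserved"
    out <- setNames(rep(0, length(cols)), cols)
    common <- intersect(cols, names(v))
    out[common] <- v[common]
    out
  }, numeric(length(cols))))
  rownames(mat) <- ids
  if (anyNA(mat)) {
    warning("unobserved families in some species; their RSCU set to 0")
    mat[is.na(mat)] <- 0
  }
  mat
}

#' Hierarchical clustering of species RSCU profiles
#'
#' Agglomerative clustering with between-group (average) linkage on squared
#' Euclidean distances — the configuration of classical RSCU clustering
#' studies. Heights are reported on the squared-distance scale. Rows are
#' ordered by species id before clustering so the result is invariant under
#' input permutation.
#'
#' @param mat Species x codon matrix from [species_rscu_matrix()].
#' @return Object of class `rscu_dendrogram`: list with `hclust` (the
#'   [stats::hclust()] tree), `merges` (data.frame: step, cluster_a,
#'   cluster_b, height — negative entries are leaves, positive are prior
#'   merges, the [stats::hclust()] convention) and `labels`.
#' @export
hierarchical_cluster <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 rows")
  if (anyDuplicated(rownames(mat))) stop("duplicate species ids")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d2 <- stats::dist(mat)^2
  hc <- stats::hclust(d2, method = "average")
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "rscu_dendrogram")
}

#' @export
print.rscu_dendrogram <- function(x, ...) {
  cat("RSCU dendrogram:", length(x$labels), "species,",
      nrow(x$merges), "merges (average linkage on squared Euclidean)\n")
  print(x$merges, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rscu_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 ylab = "height (squared Euclidean)", ...)
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived ultrametrically as (parent merge height −
#' child merge height), so every leaf sits at depth equal to the root merge
#' height on the squared-distance scale.
#'
#' @param dendro An [hierarchical_cluster()] result.
#' @param path Output file; `NULL` returns the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "rscu_dendrogram"))
  hc <- dendro$hclust
  build <- function(i) {
    # i: row of hc$merge; returns c(newick, height)
    part <- function(j) {
      if (j < 0) {
        lab <- hc$labels[-j]
        if (grepl("[ ():,;']", lab)) {
          lab <- sprintf("'%s'", gsub("'", "''", lab))
        }
        c(lab, 0)
      } else build(j)
    }
    a <- part(hc$merge[i, 1]); b <- part(hc$merge[i, 2])
    h <- hc$height[i]
    nk <- sprintf("(%s:%.12g,%s:%.12g)", a[1], h - as.numeric(a[2]),
                  b[1], h - as.numeric(b[2]))
    c(nk, h)
  }
  nwk <- paste0(build(nrow(hc$merge))[1], ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write the merge table of a dendrogram as TSV
#'
#' @param dendro An [hierarchical_cluster()] result.
#' @param path Output TSV path.
#' @export
write_merges <- function(dendro, path) {
  write.table(dendro$merges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Cophenetic distances of a dendrogram
#'
#' @param dendro An [hierarchical_cluster()] result.
#' @return A [stats::dist] of cophenetic distances (squared-distance scale).
#' @export
cophenetic_distances <- function(dendro) {
  stats::cophenetic(dendro$hclust)
}
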