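#' Run the full single-species codon-usage analysis
#'
#' Orchestrates filter -> per-gene indices -> index correlations ->
#' neutrality / ENC / PR2 diagnostics -> correspondence analysis ->
#' ENC-stratified delta-RSCU -> optimal-codon classification, and writes
#' every result table to `outdir` (TSV, 4-decimal rounding for the shaped
#' tables; a full-precision JSON sidecar accompanies them).
#'
#' @param genes A [gene_set()] (filtered or not), or a path readable by
#'   [load_sequences()].
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param filter Apply [filter_cds()] first (default TRUE).
#' @param min_length_bp,require_start Passed to [filter_cds()].
#' @param fraction Expression-stratum fraction for [stratify_by_enc()].
#' @param rscu_threshold,delta_threshold Passed to [classify_codons()].
#' @param subset Codon subset for the correspondence analysis matrix.
#' @return Invisibly, a list with `genes`, `indices`, `correlations`,
#'   `neutrality`, `enc_plot`, `pr2`, `coa`, `axis_correlations`,
#'   `strata`, `delta_rscu`, `optimal`.
#' @export
run_species_analysis <- function(genes, outdir = NULL, filter = TRUE,
                                 min_length_bp = 300, require_start = "ATG",
                                 fraction = 0.2, rscu_threshold = 1.0,
                                 delta_threshold = 0.08,
                                 subset = "codonw59") {
  if (is.character(genes)) genes <- load_sequences(genes)
  stopifnot(inherits(genes, "gene_set"))
  if (filter) {
    genes <- with_stage("filter", filter_cds(genes, min_length_bp,
                                             require_start))
  }
  indices <- with_stage("indices", usage_indices(genes))
  correlations <- with_stage("correlations", correlate_indices(indices))
  neutrality <- with_stage("neutrality", neutrality_regression(indices))
  encres <- with_stage("enc_plot", enc_plot(indices))
  pr2res <- with_stage("pr2", pr2(genes))
  mat <- with_stage("coa", rscu_matrix(genes, subset))
  # codons the gene set can never use (e.g. stops of the active code kept in
  # a standard-code subset) carry no signal; drop them before ordination
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  coares <- with_stage("coa", coa(mat))
  axcor <- with_stage("coa", axis_correlations(coares, indices))
  strata <- with_stage("optimal_codons",
                       stratify_by_enc(indices, fraction))
  drscu <- with_stage("optimal_codons", delta_rscu(genes, strata))
  optimal <- with_stage("optimal_codons",
                        classify_codons(drscu, rscu_threshold,
                                        delta_threshold))
  res <- list(genes = genes, indices = indices, correlations = correlations,
              neutrality = neutrality, enc_plot = encres, pr2 = pr2res,
              coa = coares, axis_correlations = axcor, strata = strata,
              delta_rscu = drscu, optimal = optimal)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    if (!is.null(attr(genes, "filter_report"))) {
      write_filter_report(genes, p("filter_report.tsv"))
    }
    write_indices(round_numeric(indices), p("gene_indices.tsv"))
    write_correlations(correlations, p("index_correlations.tsv"))
    write.table(round_numeric(neutrality$points), p("neutrality_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round_numeric(encres$points), p("enc_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round_numeric(encres$ratio_bins), p("enc_ratio_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round_numeric(pr2res), p("pr2_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_coa(coares, p("coa"))
    write.table(round_numeric(axcor), p("coa_axis1_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_rscu_table(drscu, p("delta_rscu.tsv"),
                     species = genes$species_id)
    write_optimal_codons(optimal, p("optimal_codons.tsv"),
                         counts = pool_counts(genes))
    jsonlite::write_json(list(
      species = genes$species_id,
      neutrality = list(slope = neutrality$slope,
                        intercept = neutrality$intercept,
                        r = neutrality$pearson_r, p = neutrality$p_value),
      mean_enc = mean(indices$ENC),
      axis1_inertia_fraction = coares$inertia_fraction[1],
      optimal_codons = rna_codon(optimal$optimal),
      high_frequency_codons = rna_codon(optimal$high_frequency),
      strata = list(high = strata$high_group, low = strata$low_group)
    ), p("summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

round_numeric <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the multi-species RSCU clustering comparison
#'
#' Builds the pooled per-species RSCU matrix, clusters it (average linkage
#' on squared Euclidean distances) and writes the matrix, the merge table
#' and a Newick tree.
#'
#' @param genesets List of filtered [gene_set()]s (>= 2 species), or a
#'   manifest data.frame with columns `species_id` and `path`
#'   ([load_sequences()] is applied to each path).
#' @param outdir Output directory; `NULL` skips file output.
#' @param subset Codon subset preset or list (see [codon_subset()]).
#' @return Invisibly, a list with `matrix` and `dendrogram`.
#' @export
run_comparative_analysis <- function(genesets, outdir = NULL,
                                     subset = "codonw59") {
  if (is.data.frame(genesets)) {
    if (!all(c("species_id", "path") %in% names(genesets))) {
      stop("manifest needs species_id and path columns")
    }
    if (anyDuplicated(genesets$species_id)) {
      stop("duplicate species ids in manifest: ",
           paste(unique(genesets$species_id[duplicated(genesets$species_id)]),
                 collapse = ", "))
    }
    genesets <- Map(function(id, path) {
      load_sequences(path, species_id = id)
    }, genesets$species_id, genesets$path)
  }
  if (length(genesets) < 2) stop("need at least 2 species")
  mat <- with_stage("rscu_matrix", species_rscu_matrix(genesets, subset))
  dendro <- with_stage("clustering", hierarchical_cluster(mat))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(species = rownames(mat),
                           round(mat, 4), check.names = FALSE),
                file.path(outdir, "species_rscu_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_merges(dendro, file.path(outdir, "cluster_merges.tsv"))
    write_newick(dendro, file.path(outdir, "rscu_dendrogram.nwk"))
  }
  invisible(list(matrix = mat, dendrogram = dendro))
}
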