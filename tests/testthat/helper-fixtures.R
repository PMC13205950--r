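# build a minimal GenBank flat file around the given genome string and
# feature table lines
write_genbank <- function(genome, feature_lines, accession = "TEST0001") {
  path <- tempfile(fileext = ".gb")
  seq_block <- vapply(seq(1, nchar(genome), 60), function(i) {
    chunk <- substr(genome, i, min(i + 59, nchar(genome)))
    grouped <- gsub("(.{10})", "\\1 ", chunk)
    sprintf("%9d %s", i, trimws(grouped))
  }, character(1))
  writeLines(c(
    sprintf("LOCUS       %s             %d bp    DNA     circular VRT",
            accession, nchar(genome)),
    "DEFINITION  synthetic test record.",
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    feature_lines,
    "ORIGIN",
    seq_block,
    "//"
  ), path)
  path
}

# a filtered-ready synthetic set used across tests
demo_geneset <- function(seed = 11, n_genes = 10, ac_weight = 2.5,
                         dispersion = 0.02, species_id = "demo") {
  spec <- synthetic_spec(
    n_genes = n_genes,
    base_profile = make_ac_biased_profile(ac_weight),
    gene_dispersion = dispersion, seed = seed
  )
  generate_geneset(spec, species_id = species_id)
}
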