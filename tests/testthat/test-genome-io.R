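test_that("genetic code tables have the expected family structure", {
  mito <- genetic_code(2)
  expect_length(mito$codon_to_aa, 64)
  expect_setequal(mito$stop_codons, c("TAA", "TAG", "AGA", "AGG"))
  expect_length(mito$sense_codons, 60)
  # family lists partition the sense codons
  expect_setequal(unlist(mito$families), mito$sense_codons)
  expect_setequal(mito$families$M, c("ATG", "ATA"))
  expect_setequal(mito$families$W, c("TGA", "TGG"))
  expect_setequal(mito$families$I, c("ATT", "ATC"))
  expect_length(mito$families$R, 4)
  expect_length(mito$families$L, 6)
  expect_length(mito$families$S, 6)

  std <- genetic_code(1)
  expect_length(std$sense_codons, 61)
  expect_setequal(std$stop_codons, c("TAA", "TAG", "TGA"))
})

test_that("FASTA loading and round trip preserve ids and sequences", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">geneA some description", "ATGAAACCC",
               ">geneB", "atgtttggau"), f)  # lowercase + U normalised
  gs <- load_sequences(f, format = "fasta", species_id = "sp1")
  expect_length(gs, 2)
  expect_identical(names(gs$genes), c("geneA", "geneB"))
  expect_identical(unname(gs$genes[["geneB"]]), "ATGTTTGGAT")

  out <- tempfile(fileext = ".fasta")
  write_fasta(gs, out)
  back <- load_sequences(out, format = "fasta", species_id = "sp1")
  expect_identical(back$genes, gs$genes)
})

test_that("GenBank CDS extraction honours strand and join locations", {
  # genome laid out so that: CDS1 plain 1..12, CDS2 minus strand,
  # CDS3 join of two exons
  genome <- paste0("ATGAAACCCGGG",              # 1..12   geneX
                   "TTTT",
                   "CATTGGGTTTCCCAT",            # 17..31  revcomp -> ATGGGAAACCCAATG
                   "AA",
                   "ATGCCC", "TT", "AAACCC")     # join(34..39,42..47)
  feats <- c(
    "     CDS             1..12",
    '                     /gene="geneX"',
    "     CDS             complement(17..31)",
    '                     /gene="geneY"',
    "     CDS             join(34..39,42..47)",
    '                     /gene="geneZ"')
  path <- write_genbank(genome, feats)
  gs <- load_sequences(path, format = "genbank")
  expect_identical(gs$species_id, "TEST0001")
  expect_identical(names(gs$genes), c("geneX", "geneY", "geneZ"))
  expect_identical(unname(gs$genes[["geneX"]]), "ATGAAACCCGGG")
  expect_identical(unname(gs$genes[["geneY"]]), "ATGGGAAACCCAATG")
  expect_identical(unname(gs$genes[["geneZ"]]), "ATGCCCAAACCC")
})

test_that("GenBank records without CDS give an empty-set warning, not failure", {
  path <- write_genbank("ATGAAACCC", character(0))
  expect_warning(gs <- load_sequences(path, format = "genbank"), "no CDS")
  expect_length(gs, 0)
})

test_that("filter_cds applies length, start, stop and duplicate rules", {
  code <- genetic_code(2)
  ok <- random_gene(code, 120)                     # 363 bp, ATG start
  short <- random_gene(code, 98)                   # 297 bp
  gtg <- sub("^ATG", "GTG", random_gene(code, 120))
  stopin <- paste0("ATG", "TAA", substr(ok, 4, nchar(ok)))
  gs <- gene_set(c(a = ok, b = short, c = gtg, d = stopin, e = ok),
                 "sp", code)
  filtered <- filter_cds(gs)
  expect_identical(names(filtered$genes), c("a"))
  rep <- attr(filtered, "filter_report")
  expect_identical(rep$reason[match(c("b", "c", "d", "e"), rep$gene_id)],
                   c("length", "start codon", "internal stop",
                     "duplicate sequence"))
  # boundary: 299 bp excluded, 300 bp kept
  g299 <- substr(random_gene(code, 100), 1, 299)
  g300 <- paste0("ATG", paste(rep("GCC", 99), collapse = ""))
  r <- attr(filter_cds(gene_set(c(x = g299, y = g300), "sp", code)),
            "filter_report")
  expect_false(r$kept[r$gene_id == "x"])
  expect_true(r$kept[r$gene_id == "y"])
})

test_that("filter_cds is idempotent and errors on an empty result", {
  set.seed(3)
  gs <- demo_geneset(seed = 3, n_genes = 6)
  once <- filter_cds(gs)
  twice <- filter_cds(once)
  expect_identical(once$genes, twice$genes)
  bad <- gene_set(c(z = "ATGAAA"), "sp", genetic_code(2))
  expect_error(filter_cds(bad), "empty after filtering")
})

test_that("translation follows the active code and handles N and stops", {
  expect_identical(translate_cds("ATGAAA", genetic_code(2)), "MK")
  expect_identical(translate_cds("ATA", genetic_code(2)), "M")
  expect_identical(translate_cds("ATA", genetic_code(1)), "I")
  expect_identical(translate_cds("ATGNNA", genetic_code(2)), "MX")
  # terminal stop trimmed; internal stop errors with a position
  expect_identical(translate_cds("ATGAAATAA", genetic_code(2)), "MK")
  expect_error(translate_cds("ATGTAAAAA", genetic_code(2)), "position 2")
  # translated length = codon count minus trailing stop
  set.seed(5)
  g <- random_gene(genetic_code(2), 50)
  expect_identical(nchar(translate_cds(paste0(g, "TAA"), genetic_code(2))),
                   nchar(g) %/% 3L)
})
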