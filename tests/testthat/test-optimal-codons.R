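test_that("ENC stratification takes the right group sizes with determinism", {
  prof <- data.frame(gene = sprintf("g%02d", 1:10), ENC = c(31:40))
  s <- stratify_by_enc(prof, 0.2)
  expect_identical(s$high_group, c("g01", "g02"))  # lowest ENC
  expect_identical(s$low_group, c("g09", "g10"))
  # 5 genes -> groups of 1 and 1
  s5 <- stratify_by_enc(prof[1:5, ], 0.2)
  expect_length(s5$high_group, 1)
  expect_length(s5$low_group, 1)
  # equal ENC -> deterministic id-ordered assignment
  tied <- data.frame(gene = c("b", "d", "a", "c", "e"), ENC = 35)
  st <- stratify_by_enc(tied, 0.2)
  expect_identical(st$high_group, "a")
  expect_identical(st$low_group, "e")
  # inverted orientation swaps groups
  si <- stratify_by_enc(prof, 0.2, invert = TRUE)
  expect_identical(si$high_group, s$low_group)
  expect_error(stratify_by_enc(prof, 0.6), "fraction")
  expect_error(stratify_by_enc(prof[1:3, ], 0.5), "overlap")
})

test_that("delta_rscu computes stratum RSCU differences", {
  code <- genetic_code(2)
  # 2-fold family used (4,0) in high and (0,4) in low -> deltas (+2, -2)
  hi <- paste(rep("TTT", 4), collapse = "")
  lo <- paste(rep("TTC", 4), collapse = "")
  gs <- gene_set(c(h = hi, l = lo), "sp", code)
  tab <- delta_rscu(gs, list(high_group = "h", low_group = "l"))
  expect_equal(tab$delta[tab$codon == "TTT"], 2)
  expect_equal(tab$delta[tab$codon == "TTC"], -2)
  expect_equal(tab$rscu_all[tab$codon == "TTT"], 1)
  # identical strata -> all deltas 0
  tab0 <- delta_rscu(gs, list(high_group = c("h", "l"),
                              low_group = c("h", "l")))
  expect_equal(tab0$delta, rep(0, nrow(tab0)))
  # delta consistent with its operands
  expect_equal(tab$delta, tab$rscu_high - tab$rscu_low)
  expect_error(delta_rscu(gs, list(high_group = character(0),
                                   low_group = "l")), "empty stratum")
  expect_error(delta_rscu(gs, list(high_group = "zz", low_group = "l")),
               "unknown gene")
})

test_that("classification applies strict thresholds and is monotone", {
  fix <- enicurus_rscu_fixture()
  tab <- fix$E_scouleri
  base <- classify_codons(tab)
  # raising either threshold never enlarges any set
  for (rt in c(1, 1.3, 1.8)) {
    for (dt in c(0.08, 0.2, 0.6)) {
      s <- classify_codons(tab, rt, dt)
      expect_true(all(s$high_frequency %in% base$high_frequency))
      expect_true(all(s$high_expression %in% base$high_expression))
      expect_true(all(s$optimal %in% base$optimal))
      expect_setequal(s$optimal,
                      intersect(s$high_frequency, s$high_expression))
    }
  }
  # all deltas below threshold -> empty optimal set
  none <- tab
  none$delta <- pmin(none$delta, 0.08)
  expect_length(classify_codons(none)$optimal, 0)
  # strictness at the boundary: delta exactly 0.08 or rscu exactly 1 excluded
  edge <- tab[1:2, ]
  edge$rscu_all <- c(1.0, 1.5)
  edge$delta <- c(0.5, 0.08)
  expect_length(classify_codons(edge)$optimal, 0)
})

test_that("optimal set is invariant under gene-order permutation", {
  gs <- demo_geneset(seed = 29)
  prof <- usage_indices(gs)
  strata <- stratify_by_enc(prof, 0.2)
  opt1 <- classify_codons(delta_rscu(gs, strata))$optimal
  perm <- sample(length(gs$genes))
  gs2 <- gene_set(gs$genes[perm], gs$species_id, gs$code)
  prof2 <- usage_indices(gs2)
  opt2 <- classify_codons(delta_rscu(gs2, stratify_by_enc(prof2, 0.2)))$optimal
  expect_setequal(opt1, opt2)
})

test_that("the delta-RSCU table round-trips through its TSV layout", {
  gs <- demo_geneset(seed = 31)
  strata <- stratify_by_enc(usage_indices(gs), 0.2)
  tab <- delta_rscu(gs, strata)
  f <- tempfile(fileext = ".tsv")
  write_rscu_table(tab, f, species = "demo")
  back <- read_rscu_table(f)[["demo"]]
  expect_identical(back$codon, tab$codon)
  expect_equal(back$rscu_all, round(tab$rscu_all, 4))
  expect_equal(back$delta, round(tab$delta, 4))
})

test_that("fixture family sums and internal consistency hold", {
  fix <- enicurus_rscu_fixture()
  for (tab in fix) {
    # the six Leu codons sum to ~6 (published rounding), all families to size
    for (aa in unique(tab$amino_acid)) {
      rows <- tab[tab$amino_acid == aa, ]
      expect_equal(sum(rows$rscu_all), nrow(rows), tolerance = 2e-3)
    }
    # printed delta equals printed high - low at the printed precision
    expect_lt(max(abs(tab$delta - (tab$rscu_high - tab$rscu_low))), 1.5e-4)
  }
})
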