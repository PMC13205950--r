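code2 <- genetic_code(2)

counts_from <- function(...) {
  x <- c(...)
  counts <- setNames(rep(0L, 64), all_codons())
  counts[names(x)] <- x
  counts
}

test_that("count_codons tallies complete codons, trims stops, skips N", {
  expect_identical(count_codons("ATGAAATAA", code2)[c("ATG", "AAA", "TAA")],
                   c(ATG = 1L, AAA = 1L, TAA = 0L))
  expect_identical(sum(count_codons("ATGAAATAA", code2)), 2L)
  expect_identical(unname(count_codons("ATGATGATG", code2)["ATG"]), 3L)
  # N codon skipped; trailing partial codon dropped
  cnt <- count_codons("ATGANAGCCTT", code2)
  expect_identical(sum(cnt), 2L)
  expect_identical(unname(cnt[c("ATG", "GCC")]), c(1L, 1L))
})

test_that("positional GC matches hand counts and pooled identity holds", {
  gc <- gc_by_position(counts_from(ATG = 1L, GCC = 1L))
  expect_equal(unname(gc), c(0.5, 0.5, 1, 2 / 3))
  expect_equal(unname(gc_by_position(counts_from(GCG = 5L, CGC = 2L))),
               c(1, 1, 1, 1))
  set.seed(8)
  for (i in 1:10) {
    cnt <- random_counts(code2)
    gc <- gc_by_position(cnt)
    expect_equal(gc[["GCall"]], mean(gc[c("GC1", "GC2", "GC3")]))
  }
  expect_error(gc_by_position(counts_from()), "no codons")
})

test_that("synonymous composition is availability-normalised", {
  # a 2-fold NNT/NNC family used as (0, k): C3s = 1 within that family
  comp <- synonymous_composition(counts_from(TTC = 7L), code2)
  expect_equal(comp[["C3s"]], 1)
  expect_equal(comp[["GC3s"]], 1)
  # uniform usage over every family: each X3s equals the availability
  # fraction computed by exhaustive enumeration over the code table
  uni <- counts_from(setNames(rep(1L, 60), code2$sense_codons))
  comp <- synonymous_composition(uni, code2)
  syn <- names(family_sizes(code2))[family_sizes(code2) >= 2]
  third <- substr(syn, 3, 3)
  aa <- code2$codon_to_aa[syn]
  for (b in c("A", "T", "G", "C")) {
    fams_with_b <- unique(aa[third == b])
    expect_equal(comp[[paste0(b, "3s")]],
                 sum(third == b) / sum(aa %in% fams_with_b))
  }
  expect_equal(comp[["GC3s"]], mean(third %in% c("G", "C")))
  # raw mode divides by all synonymous codons
  raw <- synonymous_composition(uni, code2, raw = TRUE)
  expect_equal(unname(raw[c("A3s", "T3s", "G3s", "C3s")]),
               as.numeric(table(factor(third, c("A", "T", "G", "C")))) / 60)
})

test_that("RSCU follows the definitional formula and flags absent families", {
  r <- rscu(counts_from(TTT = 3L, TTC = 1L), code2)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1.5, 0.5))
  expect_true(all(is.na(r[code2$families$A])))
  expect_equal(unname(rscu(counts_from(TTT = 3L, TTC = 1L), code2,
                           absent = "zero")[code2$families$A]),
               rep(0, 4))
  # uniform usage in every family: all RSCU = 1
  uni <- counts_from(setNames(rep(2L, 60), code2$sense_codons))
  expect_equal(unname(rscu(uni, code2)), rep(1, 60))
})

test_that("RSCU family sums equal family size on random counts (all codes)", {
  set.seed(21)
  for (code in list(code2, genetic_code(1))) {
    for (i in 1:25) {
      cnt <- random_counts(code, lambda = sample(c(2, 10, 50), 1))
      r <- rscu(cnt, code)
      for (fam in code$families) {
        if (sum(cnt[fam]) > 0) {
          expect_equal(sum(r[fam]), length(fam))
        }
      }
      # and matches the independent oracle
      expect_equal(r[names(r)], oracle_rscu(cnt, code)[names(r)])
    }
  }
})

test_that("ENC reproduces Wright's limits and homozygosity arithmetic", {
  # one 2-fold family (3,1): F = 0.5
  expect_equal(mitocub:::family_homozygosity(c(3, 1)), 0.5)
  # abundant uniform usage -> no bias -> capped at the sense-codon count
  uni <- counts_from(setNames(rep(50L, 60), code2$sense_codons))
  expect_equal(as.numeric(enc(uni, code2)), 60)
  expect_equal(as.numeric(enc(
    counts_from(setNames(rep(50L, 61), genetic_code(1)$sense_codons)),
    genetic_code(1))), 61)
  # exactly one codon used per family -> maximal bias -> 20
  one <- counts_from(setNames(
    rep(30L, length(code2$families)),
    vapply(code2$families, `[`, character(1), 1)))
  expect_equal(as.numeric(enc(one, code2)), 20)
})

test_that("ENC matches the brute-force oracle and decreases under skew", {
  set.seed(42)
  for (i in 1:60) {
    cnt <- random_counts(code2, lambda = sample(c(3, 8, 25), 1))
    expect_equal(as.numeric(enc(cnt, code2)), oracle_enc(cnt, code2),
                 tolerance = 1e-12)
  }
  # scaling counts is asymptotically neutral (the estimator is n-dependent)
  cnt <- random_counts(code2, lambda = 40)
  expect_lt(abs(as.numeric(enc(cnt * 100L, code2)) -
                as.numeric(enc(cnt * 10000L, code2))), 0.5)
  # making a uniform family maximally skewed strictly decreases Nc
  uni <- counts_from(setNames(rep(12L, 60), code2$sense_codons))
  skew <- uni
  skew[code2$families$L] <- c(72L, rep(0L, 5))
  expect_lt(as.numeric(enc(skew, code2)), as.numeric(enc(uni, code2)))
})

test_that("ENC borrows an estimate for an empty family-size class", {
  # only 2-fold families observed: 4- and 6-fold classes borrow
  cnt <- counts_from(TTT = 5L, TTC = 3L, CAT = 4L, CAC = 4L)
  nc <- enc(cnt, code2)
  expect_true(all(c("4", "6") %in% attr(nc, "borrowed_classes")))
  expect_true(as.numeric(nc) >= 20 && as.numeric(nc) <= 60)
  expect_error(enc(counts_from(TTT = 1L), code2), "too short")
})

test_that("CAI is a weighted geometric mean with the expected limits", {
  w <- reference_weights(code2)
  # only family-maximal codons -> CAI = 1
  best <- counts_from(setNames(
    rep(10L, length(code2$families)),
    vapply(code2$families, function(f) f[which.max(w[f])], character(1))))
  expect_equal(cai(best, w, code2), 1)
  # two codons with w 0.5 and 1.0 -> sqrt(0.5)
  w2 <- w
  w2["TTT"] <- 0.5; w2["TTC"] <- 1
  expect_equal(cai(counts_from(TTT = 1L, TTC = 1L), w2, code2), sqrt(0.5))
  # permutation invariance: CAI depends only on counts
  set.seed(9)
  g <- random_gene(code2, 200)
  cods <- mitocub:::split_codons(g)
  perm <- paste(sample(cods), collapse = "")
  expect_equal(cai(count_codons(g, code2), w, code2),
               cai(count_codons(perm, code2), w, code2))
  expect_error(cai(counts_from(TTT = 1L), w[-1], code2), "missing")
})

test_that("CBI and Fop match their definitions", {
  opt <- reference_optimal_codons(code2)
  all_opt <- counts_from(setNames(rep(5L, length(opt)), opt))
  expect_equal(unname(cbi_fop(all_opt, opt, code2)), c(1, 1))
  # usage exactly random -> CBI = 0
  uni <- counts_from(setNames(rep(6L, 60), code2$sense_codons))
  expect_equal(cbi_fop(uni, opt, code2)[["CBI"]], 0)
  # 2-fold family (3,1), optimal = first codon
  cnt <- counts_from(TTT = 3L, TTC = 1L)
  res <- cbi_fop(cnt, "TTT", code2)
  expect_equal(unname(res), c(0.5, 0.75))
  expect_error(cbi_fop(cnt, character(0), code2), "empty")
})

test_that("GRAVY and aromaticity follow the residue tables", {
  expect_equal(gravy_aromo("IIII")[["GRAVY"]], 4.5)
  expect_equal(gravy_aromo("FYW")[["Aromo"]], 1)
  expect_equal(gravy_aromo("IR")[["GRAVY"]], 0)
  expect_equal(gravy_aromo("IXR")[["GRAVY"]], 0)  # X excluded
  expect_error(gravy_aromo("XXX"), "no usable")
})

test_that("usage_indices assembles coherent per-gene profiles", {
  gs <- demo_geneset(seed = 13)
  prof <- usage_indices(gs)
  expect_identical(nrow(prof), 10L)
  expect_identical(prof$gene, names(gs$genes))
  expect_true(all(prof$L_sym <= prof$L_aa))
  expect_true(all(prof$GC3s >= 0 & prof$GC3s <= 1))
  expect_equal(prof$GCall, (prof$GC1 + prof$GC2 + prof$GC3) / 3)
  expect_true(all(prof$ENC >= 20 & prof$ENC <= 60))
  expect_true(all(prof$CAI > 0 & prof$CAI <= 1))
})

test_that("index correlations report r, p and handle edge cases", {
  gs <- demo_geneset(seed = 17)
  prof <- usage_indices(gs)
  cors <- correlate_indices(prof)
  expect_equal(unname(diag(cors$r)), rep(1, nrow(cors$r)))
  # a field against its negation
  prof$negENC <- -prof$ENC
  c2 <- correlate_indices(prof, fields = c("ENC", "negENC"))
  expect_equal(c2$r["ENC", "negENC"], -1)
  # constant column -> NA
  prof$const <- 1
  c3 <- correlate_indices(prof, fields = c("ENC", "const"))
  expect_true(is.na(c3$r["ENC", "const"]))
  expect_error(correlate_indices(prof[1:2, ]), "at least 3")
})
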