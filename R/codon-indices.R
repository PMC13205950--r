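#' Count codons in a coding sequence
#'
#' Tallies all complete codons of a sequence into the 64 codon slots. A
#' trailing partial codon and a complete terminal stop are trimmed first;
#' codons containing letters outside A/C/G/T (ambiguity codes such as N)
#' are skipped, not guessed.
#'
#' @param seq DNA string.
#' @param code A [genetic_code()].
#' @return Named integer vector of length 64 (codon-table order).
#' @export
count_codons <- function(seq, code = genetic_code(2)) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  cods <- split_codons(trim_terminal_stop(seq, code))
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  tab <- table(factor(cods, levels = all_codons()))
  setNames(as.integer(tab), all_codons())
}

#' Pool codon counts over the genes of a gene set
#'
#' @param genes A [gene_set()], or a list of count vectors.
#' @return Named integer vector of length 64.
#' @export
pool_counts <- function(genes) {
  if (inherits(genes, "gene_set")) {
    counts <- lapply(genes$genes, count_codons, code = genes$code)
  } else {
    counts <- genes
  }
  Reduce(`+`, counts)
}

#' Positional GC content
#'
#' GC fraction at each codon position and over all positions, computed from
#' codon counts.
#'
#' @param counts 64-slot codon count vector from [count_codons()].
#' @return Named numeric vector `c(GC1, GC2, GC3, GCall)`, fractions in
#'   `[0, 1]`.
#' @export
gc_by_position <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("no codons counted")
  cods <- names(counts)
  gc_at <- function(pos) {
    sum(counts[substr(cods, pos, pos) %in% c("G", "C")]) / n
  }
  gc <- vapply(1:3, gc_at, numeric(1))
  c(GC1 = gc[1], GC2 = gc[2], GC3 = gc[3], GCall = mean(gc))
}

#' Synonymous third-position composition
#'
#' Base composition at the third position of synonymous codons (families
#' with at least two members; stops and singleton families excluded). By
#' default each base frequency is availability-normalised: the denominator
#' for base X counts only codons whose family offers X at the third position
#' (the convention of codon-usage software). `raw = TRUE` instead divides
#' every numerator by the total synonymous-codon count.
#'
#' @param counts 64-slot codon count vector.
#' @param code A [genetic_code()].
#' @param raw Use raw proportions instead of availability-normalised ones.
#' @return Named numeric vector `c(A3s, T3s, G3s, C3s, GC3s)`.
#' @export
synonymous_composition <- function(counts, code = genetic_code(2), raw = FALSE) {
  syn <- synonymous_codons(code)
  syn_counts <- counts[syn]
  n_syn <- sum(syn_counts)
  if (n_syn == 0) stop("no synonymous codons observed")
  third <- substr(syn, 3, 3)
  fam_of <- code$codon_to_aa[syn]
  out <- numeric(4)
  names(out) <- c("A", "T", "G", "C")
  for (b in names(out)) {
    num <- sum(syn_counts[third == b])
    if (raw) {
      out[b] <- num / n_syn
    } else {
      fams_with_b <- unique(fam_of[third == b])
      denom <- sum(syn_counts[fam_of %in% fams_with_b])
      out[b] <- if (denom > 0) num / denom else NA_real_
    }
  }
  gc3s <- sum(syn_counts[third %in% c("G", "C")]) / n_syn
  c(A3s = out[["A"]], T3s = out[["T"]], G3s = out[["G"]], C3s = out[["C"]],
    GC3s = gc3s)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all members of its synonymous family were used equally:
#' `RSCU = k * x / sum(family x)` for family size k. 1 means no bias.
#'
#' @param counts 64-slot codon count vector (per gene or pooled).
#' @param code A [genetic_code()].
#' @param absent How to report codons of unobserved amino acids: `"na"`
#'   (default, flagged absent) or `"zero"`.
#' @return Named numeric vector over the code's sense codons.
#' @export
rscu <- function(counts, code = genetic_code(2), absent = c("na", "zero")) {
  absent <- match.arg(absent)
  out <- setNames(rep(NA_real_, length(code$sense_codons)), code$sense_codons)
  for (fam in code$families) {
    x <- counts[fam]
    tot <- sum(x)
    out[fam] <- if (tot > 0) length(fam) * x / tot else NA_real_
  }
  if (absent == "zero") out[is.na(out)] <- 0
  out
}

# Within-family codon homozygosity (Wright): F = (n * sum(p^2) - 1) / (n - 1)
family_homozygosity <- function(x) {
  n <- sum(x)
  if (n <= 1) return(NA_real_)
  p <- x / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (Wright's Nc)
#'
#' Summarises how far a gene's codon usage departs from uniform use of each
#' synonymous family, generalised to the family-size structure of the active
#' code: `Nc = m1 + sum_k m_k / Fbar_k`, where `m_k` is the number of k-fold
#' families in the code and `Fbar_k` the mean within-family homozygosity of
#' observed families of size k. Ranges from the number of families (maximal
#' bias) to the number of sense codons (no bias; 60 under the vertebrate
#' mitochondrial code, 61 under the standard code).
#'
#' Families with fewer than two counted codons are omitted from their class
#' mean. A class with no estimable family (or a non-positive mean) borrows
#' its estimate from the nearest estimable class k' as `Fbar_k = Fbar_k' *
#' k'/k` (exact under no bias); a missing 3-fold class with both neighbours
#' available uses `(Fbar_2 + Fbar_4) / 2`. Borrowed classes are recorded in
#' the `"borrowed_classes"` attribute.
#'
#' @param counts 64-slot codon count vector.
#' @param code A [genetic_code()].
#' @return Nc value, capped at the code's sense-codon count.
#' @export
enc <- function(counts, code = genetic_code(2)) {
  sizes <- lengths(code$families)
  fam_F <- vapply(code$families, function(fam) family_homozygosity(counts[fam]),
                  numeric(1))
  ks <- sort(unique(sizes[sizes >= 2]))
  fbar <- setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    vals <- fam_F[sizes == k & !is.na(fam_F)]
    if (length(vals) && mean(vals) > 0) fbar[as.character(k)] <- mean(vals)
  }
  if (all(is.na(fbar))) stop("gene too short: no synonymous family estimable")
  borrowed <- character(0)
  for (k in ks[is.na(fbar[as.character(ks)])]) {
    kc <- as.character(k)
    if (k == 3 && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
      fbar[kc] <- (fbar[["2"]] + fbar[["4"]]) / 2
    } else {
      est <- ks[!is.na(fbar[as.character(ks)])]
      near <- est[which.min(abs(est - k))]
      fbar[kc] <- min(1, fbar[[as.character(near)]] * near / k)
    }
    borrowed <- c(borrowed, kc)
  }
  m1 <- sum(sizes == 1)
  nc <- m1 + sum(vapply(ks, function(k) {
    sum(sizes == k) / fbar[[as.character(k)]]
  }, numeric(1)))
  nc <- min(nc, length(code$sense_codons))
  attr(nc, "borrowed_classes") <- borrowed
  nc
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over a gene's codons,
#' excluding stops and codons of single-codon families. Weights are a named
#' vector over sense codons with the family maximum equal to 1 (see
#' [reference_weights()]).
#'
#' @param counts 64-slot codon count vector.
#' @param weights Named numeric vector of relative adaptiveness in (0, 1].
#' @param code A [genetic_code()].
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, weights = reference_weights(code), code = genetic_code(2)) {
  syn <- synonymous_codons(code)
  missing <- setdiff(syn, names(weights))
  if (length(missing)) {
    stop("weights missing for codons: ", paste(missing, collapse = ", "))
  }
  x <- counts[syn]
  n <- sum(x)
  if (n == 0) stop("no synonymous codons observed")
  exp(sum(x * log(weights[syn])) / n)
}

#' Codon bias index and frequency of optimal codons
#'
#' Both measure use of a designated optimal-codon subset over the gene's
#' synonymous codons (families of size >= 2): `Fop = N_opt / N_syn`;
#' `CBI = (N_opt - N_rand) / (N_syn - N_rand)` where `N_rand` is the
#' expected optimal-codon count under equal within-family usage.
#'
#' @param counts 64-slot codon count vector.
#' @param optimal_set Character vector of optimal codons (subset of the
#'   code's sense codons).
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(CBI, Fop)`.
#' @export
cbi_fop <- function(counts, optimal_set = reference_optimal_codons(code),
                    code = genetic_code(2)) {
  if (!length(optimal_set)) stop("optimal set is empty")
  bad <- setdiff(optimal_set, code$sense_codons)
  if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
  syn_fams <- code$families[lengths(code$families) >= 2]
  n_syn <- 0; n_opt <- 0; n_rand <- 0
  for (fam in syn_fams) {
    nf <- sum(counts[fam])
    n_syn <- n_syn + nf
    n_opt <- n_opt + sum(counts[intersect(fam, optimal_set)])
    n_rand <- n_rand + nf * length(intersect(fam, optimal_set)) / length(fam)
  }
  if (n_syn == 0) stop("no synonymous codons observed")
  cbi <- if (n_syn == n_rand) NA_real_ else (n_opt - n_rand) / (n_syn - n_rand)
  c(CBI = cbi, Fop = n_opt / n_syn)
}

#' Hydropathy and aromaticity of a protein
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy over residues; aromaticity is
#' the fraction of Phe/Tyr/Trp. `X` residues are excluded from both.
#'
#' @param protein Amino-acid string (no stops).
#' @return Named numeric vector `c(GRAVY, Aromo)`.
#' @export
gravy_aromo <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  aa <- aa[aa != "X"]
  if (!length(aa)) stop("no usable residues")
  unknown <- setdiff(aa, names(KYTE_DOOLITTLE))
  if (length(unknown)) {
    stop("unknown residues: ", paste(unique(unknown), collapse = ", "))
  }
  c(GRAVY = mean(KYTE_DOOLITTLE[aa]),
    Aromo = mean(aa %in% c("F", "Y", "W")))
}

#' Per-gene codon usage indices
#'
#' Computes the full index profile for every gene of a set: synonymous
#' third-position composition, ENC, CAI, CBI, Fop, GRAVY, aromaticity,
#' codon counts (L_sym = codons in families of size >= 2, L_aa =
#' translatable codons) and positional GC.
#'
#' @param genes A filtered [gene_set()].
#' @param weights CAI reference weights; default [reference_weights()].
#' @param optimal_set Optimal codons for CBI/Fop; default
#'   [reference_optimal_codons()].
#' @return data.frame with one row per gene and columns gene, T3s, C3s,
#'   A3s, G3s, GC3s, ENC, CAI, CBI, Fop, GRAVY, Aromo, L_sym, L_aa, GC1,
#'   GC2, GC3, GCall.
#' @export
usage_indices <- function(genes, weights = reference_weights(genes$code),
                          optimal_set = reference_optimal_codons(genes$code)) {
  stopifnot(inherits(genes, "gene_set"))
  code <- genes$code
  syn <- synonymous_codons(code)
  rows <- lapply(names(genes$genes), function(id) {
    counts <- count_codons(genes$genes[[id]], code)
    comp <- synonymous_composition(counts, code)
    gc <- gc_by_position(counts)
    cf <- cbi_fop(counts, optimal_set, code)
    ga <- gravy_aromo(translate_cds(genes$genes[[id]], code))
    data.frame(
      gene = id,
      T3s = comp[["T3s"]], C3s = comp[["C3s"]], A3s = comp[["A3s"]],
      G3s = comp[["G3s"]], GC3s = comp[["GC3s"]],
      ENC = as.numeric(enc(counts, code)),
      CAI = cai(counts, weights, code),
      CBI = cf[["CBI"]], Fop = cf[["Fop"]],
      GRAVY = ga[["GRAVY"]], Aromo = ga[["Aromo"]],
      L_sym = sum(counts[syn]), L_aa = sum(counts[code$sense_codons]),
      GC1 = gc[["GC1"]], GC2 = gc[["GC2"]], GC3 = gc[["GC3"]],
      GCall = gc[["GCall"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlations among usage indices
#'
#' @param profiles data.frame from [usage_indices()] (>= 3 genes).
#' @param fields Index columns to correlate.
#' @return Object of class `index_correlations`: list with matrices `r` and
#'   `p` (two-sided, exact t transform with n-2 df) and `stars`
#'   (`"**"` p < 0.01, `"*"` p < 0.05). Constant columns give NA.
#' @export
correlate_indices <- function(profiles,
                              fields = c("T3s", "C3s", "A3s", "G3s", "GC3s",
                                         "ENC", "CAI", "CBI", "Fop", "GRAVY",
                                         "Aromo", "GC1", "GC2", "GC3", "GCall")) {
  fields <- intersect(fields, names(profiles))
  if (nrow(profiles) < 3) stop("need at least 3 genes")
  k <- length(fields)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(fields, fields))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- profiles[[fields[i]]]; y <- profiles[[fields[j]]]
      if (sd(x) == 0 || sd(y) == 0) next
      ct <- cor.test(x, y, method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(fields, fields))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars), class = "index_correlations")
}

#' @export
print.index_correlations <- function(x, digits = 2, ...) {
  cat("Pearson correlations (", nrow(x$r), " indices); * p<0.05, ** p<0.01\n",
      sep = "")
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write per-gene indices or a correlation matrix as TSV
#'
#' @param profiles data.frame from [usage_indices()].
#' @param path Output TSV path.
#' @export
write_indices <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indices
#' @param correlations Object from [correlate_indices()].
#' @export
write_correlations <- function(correlations, path) {
  f <- rownames(correlations$r)
  idx <- which(upper.tri(correlations$r), arr.ind = TRUE)
  df <- data.frame(
    index_a = f[idx[, 1]], index_b = f[idx[, 2]],
    r = correlations$r[idx], p = correlations$p[idx],
    significance = correlations$stars[idx], stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
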