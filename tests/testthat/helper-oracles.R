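# Independent oracles, coded straight from first principles and kept free of
# the package's internals.

# Wright's Nc, family by family: F_aa = (n * sum(p^2) - 1) / (n - 1), class
# averages over the code's family-size structure. Returns NA when any
# family-size class has no estimable family (the oracle does no borrowing).
oracle_enc <- function(counts, code) {
  sizes <- lengths(code$families)
  Fs <- ns <- setNames(numeric(length(code$families)), names(code$families))
  for (aa in names(code$families)) {
    x <- counts[code$families[[aa]]]
    n <- sum(x)
    ns[aa] <- n
    Fs[aa] <- if (n <= 1) NA_real_ else {
      p <- x / n
      (n * sum(p^2) - 1) / (n - 1)
    }
  }
  nc <- sum(sizes == 1)
  for (k in sort(unique(sizes[sizes >= 2]))) {
    vals <- Fs[sizes == k]
    vals <- vals[!is.na(vals)]
    if (!length(vals) || mean(vals) <= 0) return(NA_real_)
    nc <- nc + sum(sizes == k) / mean(vals)
  }
  min(nc, sum(sizes[sizes >= 2]) + sum(sizes == 1))
}

# RSCU by definition: per family, observed / (total / family size)
oracle_rscu <- function(counts, code) {
  out <- c()
  for (fam in code$families) {
    tot <- sum(counts[fam])
    expected <- tot / length(fam)
    out[fam] <- if (tot > 0) counts[fam] / expected else NA_real_
  }
  out
}

# classical CA through the eigen-decomposition of the row-profile operator
oracle_ca <- function(mat) {
  n <- sum(mat)
  P <- mat / n
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  k <- min(dim(mat)) - 1
  lambda <- pmax(ev$values[seq_len(k)], 0)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  F <- diag(1 / sqrt(r)) %*% U %*% diag(sqrt(lambda), k)
  list(inertia = lambda, total_inertia = sum(ev$values[ev$values > 1e-12]),
       row_coords = F)
}

# chi-square statistic of a contingency-style table (for the inertia check)
oracle_chisq <- function(mat) {
  n <- sum(mat)
  E <- outer(rowSums(mat), colSums(mat)) / n
  sum((mat - E)^2 / E)
}

# random 64-slot codon count table in which every family of the code is
# observed with at least `min_per_family` codons
random_counts <- function(code, lambda = 30, min_per_family = 2) {
  counts <- setNames(rep(0L, 64), all_codons())
  for (fam in code$families) {
    repeat {
      x <- rpois(length(fam), lambda)
      if (sum(x) >= min_per_family) break
    }
    counts[fam] <- x
  }
  counts
}

# short random coding sequence built from explicit codons (no stops inside)
random_gene <- function(code, n_codons = 80) {
  cods <- sample(code$sense_codons, n_codons, replace = TRUE)
  paste(c("ATG", cods), collapse = "")
}
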