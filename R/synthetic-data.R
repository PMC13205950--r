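#' Specification for a synthetic gene set
#'
#' Describes a set of coding sequences with controlled codon-usage
#' structure: amino acids are drawn from `aa_composition`, codons within
#' each synonymous family from a per-gene profile derived from
#' `base_profile`. Defaults emulate a small mitochondrial gene set: 10
#' genes of 100-610 codons (roughly 300-1800 bp, the span of real
#' mitochondrial protein-coding genes).
#'
#' @param n_genes Number of genes (default 10).
#' @param length_range_codons Integer range of gene lengths in codons,
#'   start codon included (default `c(100, 610)`).
#' @param base_profile Named list: amino acid -> probability vector over
#'   its family's codons (see [make_ac_biased_profile()]); default uniform
#'   within every family.
#' @param gene_dispersion Non-negative scalar controlling per-gene
#'   perturbation of `base_profile`: 0 (default) means every gene uses the
#'   base profile exactly; larger values draw each gene's family profile
#'   from a Dirichlet with concentration `base_profile / gene_dispersion`,
#'   so dispersion grows with the value.
#' @param aa_composition Probability vector over amino acids; `"uniform"`
#'   (default) or `"mito-like"` (enriched for Leu/Ile/Thr/Ala as in real
#'   mitochondrial proteomes), or a named numeric vector.
#' @param code A [genetic_code()].
#' @param seed Integer seed driving all draws.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 10, length_range_codons = c(100, 610),
                           base_profile = NULL, gene_dispersion = 0,
                           aa_composition = "uniform",
                           code = genetic_code(2), seed = 1) {
  stopifnot(n_genes >= 1, length(length_range_codons) == 2,
            length_range_codons[1] >= 2, gene_dispersion >= 0)
  if (is.null(base_profile)) base_profile <- make_ac_biased_profile(1, code)
  check_profile(base_profile, code)
  aa_composition <- resolve_aa_composition(aa_composition, code)
  structure(list(
    n_genes = as.integer(n_genes),
    length_range_codons = as.integer(length_range_codons),
    base_profile = base_profile, gene_dispersion = gene_dispersion,
    aa_composition = aa_composition, code = code, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

check_profile <- function(profile, code) {
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    p <- profile[[aa]]
    if (is.null(p)) stop("profile missing amino acid ", aa)
    if (!setequal(names(p), fam)) {
      extra <- setdiff(names(p), fam)
      if (length(intersect(extra, code$stop_codons))) {
        stop("profile puts probability on a stop codon: ",
             paste(intersect(extra, code$stop_codons), collapse = ", "))
      }
      stop("profile codons for ", aa, " do not match the family")
    }
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("profile for ", aa, " is not a probability vector")
    }
  }
  invisible(TRUE)
}

resolve_aa_composition <- function(x, code) {
  aas <- names(code$families)
  if (is.character(x) && length(x) == 1) {
    if (x == "uniform") {
      return(setNames(rep(1 / length(aas), length(aas)), aas))
    }
    if (x == "mito-like") {
      w <- setNames(rep(1, length(aas)), aas)
      w[c("L", "I", "T", "A")] <- c(4, 2.5, 2, 2)  # Leu/Ile/Thr/Ala-rich
      return(w / sum(w))
    }
    stop("unknown composition preset: ", x)
  }
  if (!setequal(names(x), aas) || abs(sum(x) - 1) > 1e-8 || any(x < 0)) {
    stop("aa_composition must be a probability vector over the code's amino acids")
  }
  x[aas]
}

#' A/C-third-position-biased codon profile
#'
#' Within each synonymous family, codons ending in A or C get weight
#' `ac_weight` and the rest weight 1, normalised to probabilities. Weight 1
#' gives the uniform profile; large weights drive T/G-ending usage toward
#' zero, mimicking the third-position A/C enrichment of avian mitochondrial
#' genes.
#'
#' @param ac_weight Weight (>= 1) for A/C-ending codons.
#' @param code A [genetic_code()].
#' @return Named list: amino acid -> named probability vector.
#' @export
make_ac_biased_profile <- function(ac_weight = 1, code = genetic_code(2)) {
  stopifnot(ac_weight >= 1)
  lapply(code$families, function(fam) {
    w <- ifelse(substr(fam, 3, 3) %in% c("A", "C"), ac_weight, 1)
    setNames(w / sum(w), fam)
  })
}

#' Maximal-bias codon profile
#'
#' Probability 1 on a single codon per family (the first in codon-table
#' order); drives every gene's ENC to the number of families.
#'
#' @param code A [genetic_code()].
#' @return Named list: amino acid -> named probability vector.
#' @export
make_one_codon_profile <- function(code = genetic_code(2)) {
  lapply(code$families, function(fam) {
    setNames(c(1, rep(0, length(fam) - 1)), fam)
  })
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic gene set
#'
#' Draws every gene of the specification: an ATG start, amino acids from
#' the composition, codons from the gene-level profile (the base profile,
#' perturbed per gene when `gene_dispersion > 0`), and a terminal stop from
#' the code's stop set. Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param species_id Species label for the gene set.
#' @return A [gene_set()] with attribute `truth`: list with the spec, the
#'   seed, and `gene_profiles` (realised per-gene codon probabilities).
#' @export
generate_geneset <- function(spec, species_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- spec$code
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  aas <- names(code$families)
  genes <- character(spec$n_genes)
  profiles <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    prof <- if (spec$gene_dispersion == 0) spec$base_profile else {
      lapply(spec$base_profile, function(p) {
        setNames(rdirichlet1(pmax(p, 1e-12) / spec$gene_dispersion), names(p))
      })
    }
    profiles[[i]] <- prof
    rng <- spec$length_range_codons
    len <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    aa_seq <- sample(aas, len - 1, replace = TRUE, prob = spec$aa_composition)
    cods <- character(length(aa_seq))
    for (aa in unique(aa_seq)) {
      idx <- which(aa_seq == aa)
      fam <- code$families[[aa]]
      cods[idx] <- if (length(fam) == 1) fam
                   else sample(fam, length(idx), replace = TRUE,
                               prob = prof[[aa]])
    }
    stop_cod <- sample(code$stop_codons, 1)
    genes[i] <- paste(c("ATG", cods, stop_cod), collapse = "")
  }
  names(genes) <- sprintf("gene%02d", seq_len(spec$n_genes))
  names(profiles) <- names(genes)
  out <- gene_set(genes, species_id, code)
  attr(out, "truth") <- list(spec = spec, seed = spec$seed,
                             gene_profiles = profiles)
  out
}

#' Write the truth record of a synthetic gene set as JSON
#'
#' @param genes A [generate_geneset()] result.
#' @param path Output JSON path.
#' @export
write_truth <- function(genes, path) {
  truth <- attr(genes, "truth")
  if (is.null(truth)) stop("gene set has no truth record")
  spec <- truth$spec
  jsonlite::write_json(list(
    seed = truth$seed, n_genes = spec$n_genes,
    length_range_codons = spec$length_range_codons,
    gene_dispersion = spec$gene_dispersion,
    table_id = spec$code$table_id,
    aa_composition = as.list(spec$aa_composition),
    base_profile = lapply(spec$base_profile, as.list),
    gene_profiles = lapply(truth$gene_profiles,
                           function(p) lapply(p, as.list))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
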