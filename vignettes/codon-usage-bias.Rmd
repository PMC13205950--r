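---
title: "Analysing codon usage bias in mitochondrial protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing codon usage bias in mitochondrial protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

## The problem

Synonymous codons are not used at random. In a mitochondrial genome the
usage pattern of each protein-coding gene carries the joint signature of
mutation pressure (which pushes base composition, especially at the third
codon position) and natural selection (which favours codons matching the
tRNA pool and translational demands). `mitocub` implements the standard
battery of per-gene indices and diagnostics used to dissect this signal
in small gene sets — typically the ~10 core protein-coding genes of a
vertebrate mitogenome — plus the downstream procedures built on them:
optimal-codon identification from expression strata and multi-species
RSCU clustering.

All computations default to NCBI translation table 2 (vertebrate
mitochondrial: stops UAA/UAG/AGA/AGG, AUA = Met, UGA = Trp, hence 60
sense codons in 20 families and no single-codon family). Table 1 (the
standard code) is selectable everywhere through `genetic_code(1)`.

## Input handling and filtering

`load_sequences()` reads FASTA or GenBank flat files (CDS features are
extracted with strand and `join()` handling; `/gene` or `/product`
qualifiers name the genes). `filter_cds()` applies the conventional
quality rules: minimum length 300 bp, ATG initiator, no internal stop
codon under the active code, and no exact duplicate of an already
retained gene. The duplicate rule is our deterministic operationalisation
of excluding "repetitive" sequences; no repeat masking is attempted. Each
exclusion is recorded with its reason in a filter report, so which rule
fired for which gene is auditable. Mitochondrial CDS often end on an
incomplete stop codon completed by polyadenylation; a trailing partial
codon and a complete terminal stop are trimmed before any counting, and
codons containing ambiguity letters (N) are skipped rather than guessed.

## The indices

For each gene, `usage_indices()` computes:

* **Positional GC** (GC1, GC2, GC3, GCall): fractions of G/C at each
  codon position; GCall is their mean by construction.
* **Synonymous third-position composition** (A3s, T3s, G3s, C3s, GC3s):
  computed over families of size ≥ 2 only. Each base frequency is
  *availability-normalised* — the denominator for base X counts only the
  codons whose family offers X at the third position — matching the
  semantics of the classical codon-usage tools; a raw-proportion variant
  is available via `synonymous_composition(..., raw = TRUE)`.
* **RSCU**: `k * x / sum(family)` for family size `k`; 1 means no bias.
  Families with zero total are reported as absent (`NA`) rather than 0,
  except where a 0 is the documented convention (pooled stratum tables,
  species matrices).
* **ENC** (Wright's effective number of codons), generalised to the
  family structure of the active code:
  `Nc = m1 + sum_k m_k / Fbar_k`, with the within-family homozygosity
  `F = (n * sum(p^2) - 1) / (n - 1)`. Families with fewer than two
  counted codons are omitted from their class mean. When a whole
  family-size class is unestimable (short genes can miss the 6-fold
  estimate), the class borrows from the nearest estimable class `k'` as
  `Fbar_k = Fbar_k' * k'/k`, which is exact under no bias, clamped at 1;
  a missing 3-fold class with both neighbours present uses
  `(Fbar_2 + Fbar_4)/2`, Wright's recommendation. Borrowing is recorded
  in the result's `borrowed_classes` attribute. The value is capped at
  the code's sense-codon count — 60 under table 2, although the
  literature's "20 to 61" phrasing refers to the standard code's scale.
* **CAI, CBI, Fop**: all three depend on a reference. The default,
  `reference_weights()`, is the classical *E. coli*
  highly-expressed-gene relative-adaptiveness set (after Sharp & Li
  1987) — the default reference of the classical command-line tools —
  re-normalised within the active code's families so each family
  maximum is 1, with a 0.01 floor for codons the source table does not
  cover (such as UGA, a sense codon only in the mitochondrial code).
  Absolute values of these indices are only meaningful relative to this
  choice; all three functions accept user-supplied weights or optimal
  sets.
* **GRAVY and aromaticity** of the translated product (Kyte–Doolittle
  means; F/Y/W fraction), with X residues excluded.
* **L_sym** (codons in families of size ≥ 2) and **L_aa** (translatable
  codons).

`correlate_indices()` gives the pairwise Pearson matrix with two-sided
p-values from the exact t transform on n − 2 degrees of freedom, starred
at 0.05/0.01.

## Selection-versus-mutation diagnostics

**Neutrality plot** (`neutrality_regression()`): ordinary least squares
of GC12 on GC3. A slope near 1 with significant correlation indicates
mutation pressure; near 0, selection. The qualitative flag uses
|slope − 1| < 0.25 and p < 0.05 — the literature gives only qualitative
guidance, so the band is a package choice, reported transparently in the
result.

**ENC plot** (`enc_plot()`): observed ENC against the mutation-only
expectation `ENC_exp = 2 + g + 29/(g^2 + (1-g)^2)` at `g = GC3s`, and
the ENC ratio `(ENC_exp − ENC_obs)/ENC_exp`. Ratios are binned into
contiguous half-open 0.05-wide classes (`[0.205, 0.255)`,
`[0.255, 0.305)`, ...) labelled with the conventional two-decimal class
names; the published tables print the first class as "0.20–0.25" and we
keep that label. Bins extend automatically when values fall outside the
conventional range, and frequencies always sum to 1.

**PR2 plot** (`pr2()`): per-gene `x = G3/(G3+C3)` against
`y = A3/(A3+T3)` over synonymous third positions by default (the
all-codon variant is a flag, since sources rarely state which was used);
(0.5, 0.5) is strand-parity equilibrium, and each point gets a quadrant
label and its deviation from the centre.

## Correspondence analysis

`coa()` is classical correspondence analysis of the gene × codon RSCU
matrix: scale to a correspondence table, form standardised residuals,
decompose by SVD, return principal coordinates and per-axis inertia
fractions. SVD sign indeterminacy is resolved by forcing the
largest-magnitude row coordinate on each axis positive, so outputs are
deterministic; correlations of Axis 1 with the usage indices
(`axis_correlations()`) are sign-convention dependent in sign but not in
magnitude. Codons a mitochondrial gene set can never use (e.g. AGA/AGG
retained by the standard-code 59-codon subset) are structurally zero
columns and are dropped before ordination.

## Optimal codons

`stratify_by_enc()` sorts genes by ENC and takes the extreme
`fraction = 0.2` at each end, group size `max(1, round(fraction * n))`
(2 + 2 for a ten-gene set), ties broken by gene id. Following the
Wright/Sharp convention that stronger bias proxies higher expression,
the *lowest*-ENC genes form the putative high-expression group; the
wording in parts of the literature is ambiguous, so `invert = TRUE`
swaps the orientation. `delta_rscu()` computes pooled RSCU for the full
set and both strata (unobserved families get 0 in a stratum), and
`classify_codons()` applies the strict thresholds: high-frequency
RSCU > 1, high-expression ΔRSCU > 0.08, optimal = both.

## Multi-species RSCU clustering

`species_rscu_matrix()` pools counts within species and restricts
columns to a codon subset: `"codonw59"` (64 − UAA/UAG/UGA − AUG − UGG,
the 59-codon convention of the classical tools, kept even though the
mitochondrial code has 60 sense codons and no single-codon families,
because that is the convention comparative studies state) or `"mito60"`
(the table-2 sense set), or an explicit list. `hierarchical_cluster()`
runs average ("between-group") linkage on *squared* Euclidean distances
— the SPSS configuration of the comparative literature — and reports
heights on the squared scale without re-squaring inside the linkage.
Rows are sorted by species id first, making the tree invariant under
input order. `write_newick()` exports an ultrametric tree whose branch
lengths are parent-minus-child merge heights, so leaves align at the
root height.

## The synthetic generator

`generate_geneset()` draws gene sets with controlled usage structure so
the full pipeline is testable without any download: amino acids from a
composition (`"uniform"`, or `"mito-like"` enriched for Leu/Ile/Thr/Ala
as in real mitochondrial proteomes), codons within each family from a
base profile (e.g. `make_ac_biased_profile(2.5)`, which up-weights
A/C-ending codons the way avian mitogenomes favour them), an ATG start,
and a terminal stop from the active code's stop set. `gene_dispersion`
perturbs the profile per gene through a Dirichlet draw (0 = all genes
share the profile exactly). Default gene lengths are 100–610 codons,
the span of real mitochondrial protein-coding genes (roughly 300–1800
bp). All draws flow from one seed; the realised per-gene profiles are
returned as a truth record for parameter-recovery checks.

What the generator does *not* emulate: phylogenetic correlation between
genes or species, within-gene positional structure, amino-acid
composition differences between genes, and sequencing artefacts. Tests
passing on synthetic data therefore validate the estimators and the
plumbing, not any biological claim about real mitogenomes.

## Numerical and testing choices

* Problem sizes in the test-suite are kept small (ten-gene sets of
  100–610 codons) except for the law-of-large-numbers recovery check,
  which uses ten genes of 10^5 codons each: at that size the 0.05
  sup-norm bound on pooled RSCU sits at roughly five standard errors
  even for the 6-fold families, so the check is a genuine consistency
  test rather than a coin flip.
* Published reference values for the two *Enicurus* species' RSCU table
  ship as a plain-text fixture (`enicurus_rscu_fixture()`); replaying
  it through `classify_codons()` reproduces the published
  high-frequency/optimal codon sets exactly. The printed table has two
  rows (Phe UUU/UUC and Pro CCG for the second species) whose values
  exceed 1 in apparent conflict with the accompanying text's claim that
  all high-frequency codons end in A/C; the fixture keeps the printed
  numbers and tests pin the A/C breakdown for the first species only.
* Accession-dependent end-to-end checks (pooled GCall, mean ENC,
  neutrality slope, ENC-ratio binning, Axis-1 inertia) run whenever the
  GenBank flat files for the two mitogenome accessions are placed under
  `inst/extdata/accessions/`; they are user-supplied inputs and are not
  bundled, so those tests report a failure with instructions until the
  files are provided.
* Exact reproduction of published correspondence-analysis inertia
  percentages can additionally depend on the internal codon-set trimming
  of the original tool, which is why the Axis-1 check carries a
  percentage-point tolerance.

## A worked example

```{r example, eval = FALSE}
library(mitocub)

spec <- synthetic_spec(
  n_genes = 10,
  base_profile = make_ac_biased_profile(2.5),
  gene_dispersion = 0.05,
  aa_composition = "mito-like",
  seed = 1
)
genes <- generate_geneset(spec)
res <- run_species_analysis(genes, outdir = "results_demo")

res$neutrality          # slope, r, p, interpretation
res$enc_plot            # points + ENC-ratio class table
res$optimal             # high-frequency / high-expression / optimal codons
```

## Limitations

The package quantifies bias and its standard diagnostics; it does not
fit an explicit population-genetic model of selection, does not infer
phylogenies (the comparative module stops at the RSCU dendrogram), and
its CAI/CBI/Fop values inherit whatever reference set is supplied.
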