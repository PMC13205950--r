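# mitocub

Codon usage bias analysis for mitochondrial protein-coding genes.

Synonymous codons are used unevenly, and in mitochondrial genomes that
unevenness carries the joint signature of mutation pressure and natural
selection. `mitocub` is for molecular evolution researchers who want the
standard per-gene codon-usage battery — and the procedures built on it —
as tested, scriptable R functions rather than a chain of one-off desktop
tools:

* **Per-gene indices** — positional GC, availability-normalised
  synonymous third-position composition (A3s/T3s/G3s/C3s, GC3s), RSCU
  (`RSCU = k·x / Σ_family x`), Wright's effective number of codons
  (`Nc = m₁ + Σ_k m_k / F̄_k` with `F = (nΣp² − 1)/(n − 1)`), CAI, CBI,
  Fop, GRAVY, aromaticity, with a Pearson correlation matrix across
  genes.
* **Selection-vs-mutation diagnostics** — the neutrality plot (OLS of
  GC12 on GC3), the ENC plot against
  `ENC_exp = 2 + GC3s + 29/(GC3s² + (1 − GC3s)²)` with ENC-ratio class
  binning, and the PR2 parity plot (`A3/(A3+T3)` vs `G3/(G3+C3)`).
* **Correspondence analysis** of the gene × codon RSCU matrix with
  per-axis inertia fractions and Axis-1/index correlations.
* **Optimal codons** — genes stratified by ENC into putative high/low
  expression groups (top and bottom 20%), pooled
  `ΔRSCU = RSCU_high − RSCU_low`, and classification: high-frequency
  (RSCU > 1), high-expression (ΔRSCU > 0.08), optimal (both).
* **Multi-species RSCU clustering** — pooled per-species RSCU over a
  59- or 60-codon subset, average ("between-group") linkage on squared
  Euclidean distances, Newick export.
* **A seeded synthetic generator** of coding sequences with
  controllable per-family codon probabilities, so the entire pipeline
  runs and is testable with no downloads.

Everything defaults to the vertebrate mitochondrial code (translation
table 2: stops UAA/UAG/AGA/AGG, AUA = Met, UGA = Trp); the standard code
is available via `genetic_code(1)`. Inputs are FASTA or GenBank flat
files (CDS features extracted with strand/`join()` handling).

## A worked example

Replay the packaged two-species reference RSCU table through the
optimal-codon procedure:

```r
library(mitocub)
fix <- enicurus_rscu_fixture()
classify_codons(fix$E_scouleri)
```

```
Codon classification (RSCU > 1, deltaRSCU > 0.08):
  high-frequency (27): GCC GCA UGC GAC GAA UUC GGA CAC AUC AAA CUC CUA AUA AAC CCA CCC CAA CGA UCC UCA AGC ACC ACA GUC GUA UGA UAC
  high-expression (24)
  optimal (16): GCC GAA CAC AUC AAA CUA AAC CCA CCC CAA CGA UCC AGC ACC ACA GUA
```

27 codons exceed RSCU 1 (13 A-ending, 14 C-ending — the A/C bias typical
of avian mitogenomes), 24 exceed ΔRSCU 0.08, and the 16 in both sets are
the optimal codons.

Run the full single-species pipeline on a synthetic A/C-biased ten-gene
set:

```r
spec <- synthetic_spec(n_genes = 10,
                       base_profile = make_ac_biased_profile(2.5),
                       gene_dispersion = 0.05,
                       aa_composition = "mito-like", seed = 1)
genes <- generate_geneset(spec)
res <- run_species_analysis(genes, outdir = "results_demo")
res$neutrality
res$enc_plot
```

```
Neutrality plot: GC12 = 0.2307 + 0.3801 * GC3 (r = 0.4694, p = 0.1711)
  interpretation: selection-dominant
ENC plot: 10 genes; 10 below the expected curve
     class  mid count frequency
 0.01–0.05 0.03     1       0.1
 0.06–0.10 0.08     1       0.1
 0.11–0.15 0.13     0       0.0
 0.16–0.20 0.18     4       0.4
 0.20–0.25 0.23     3       0.3
 ...
```

The shallow, non-significant neutrality slope and every gene sitting
below the expected ENC curve are exactly the pattern injected by the
A/C-skewed generating profile: usage bias beyond what composition alone
explains. `run_species_analysis()` writes all tables (gene indices,
correlations, diagnostics, ordination, ΔRSCU, optimal codons) as TSV
plus a JSON summary into `outdir`; `run_comparative_analysis()` does the
multi-species matrix, dendrogram, and Newick tree. A thin command-line
wrapper with `analyze` / `compare` / `simulate` / `replay-fixture`
subcommands ships at `inst/scripts/mitocub-cli.R`.

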