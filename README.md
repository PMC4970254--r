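# mirtriad

Integrative miRNA–mRNA–phenotype correlation networks for two-group
(e.g. two-breed) muscle transcriptomics studies.

## What it does and for whom

Studies that profile both microRNAs and mRNAs in the same animals, together
with physiological measurements, ask a recurring question: which miRNAs
plausibly regulate which genes, and which of those regulations track a
phenotype? `mirtriad` is for analysts of such designs. It implements the
full integration pipeline as tested R functions:

1. **Probe filtering** — detection ("present") calls at ≥ 70% of samples
   within each group (inclusive, conjunctive by default) and a ≤ 29 nt
   probe-sequence length filter (`presence_filter()`, `length_filter()`).
2. **Differential expression** — per-probe one-way fixed-effect ANOVA on
   group, Benjamini–Hochberg FDR, fold change as 2^|Δlog2| with direction,
   mature-level collapse (`anova_fixed_effect()`, `bh_fdr()`,
   `select_de()`, `collapse_to_mature()`).
3. **Target prediction** — TargetScan-style seed matching (miRNA positions
   2–8, site types 6mer / 7mer-A1 / 7mer-m8 / 8mer, over 5'UTR, CDS and
   3'UTR) and an RNAhybrid-style intermolecular duplex minimum-free-energy
   dynamic program (nearest-neighbor stacking, loops ≤ 4 nt per side,
   −25 kcal/mol cutoff, one hit per transcript), combined by union or
   intersection (`find_seed_matches()`, `duplex_mfe()`,
   `predict_targets()`).
4. **Correlation screening** — all pairwise Pearson correlations
   (miRNA × mRNA, molecule × 19 traits, gene panels, qPCR-vs-array
   concordance) with two-sided p from t = r·√(n−2)/√(1−r²) and family-wise
   BH q-values (`correlate_all()`, `correlate_with_phenotypes()`,
   `qpcr_concordance()`).
5. **Network assembly** — negatively correlated, target-supported
   miRNA–mRNA pairs; miRNA–gene–trait triads; per-trait top-10 reports;
   cross-list correlation matrices; GraphML/SIF export
   (`integrate_de_pairs()`, `build_triads()`, `top_pairs_per_trait()`,
   `crosslist_correlation()`, `export_graph()`).
6. **Enrichment** — one-sided Fisher-exact (hypergeometric)
   over-representation against GMT gene sets (`fisher_enrichment()`).

A synthetic-study generator (`sim_config()`, `generate_dataset()`) creates
a complete two-group study — expression with planted breed effects,
transcripts with planted complementary target sites, negative
miRNA→target couplings, and 19 latent-factor-driven traits — with ground
truth, so the whole pipeline is testable end to end without downloading
anything.

## The statistics at the core

For a miRNA *m*, gene *g* and trait *y*, a reported **triad** requires

* cor(m, y) significant (p < 0.05) and cor(g, y) significant,
* cor(m, g) < 0 with p < 0.05,
* *g* a predicted target of *m* (seed match and/or duplex MFE ≤ −25
  kcal/mol),

with Pearson p-values from the t transform (df = n − 2) and BH step-up
q-values, q(i) = min over j ≥ i of m·p(j)/j, on declared families. The
duplex energy is the minimum over antiparallel, non-crossing
intermolecular pairings of Σ stacking + Σ loop penalties + initiation +
terminal AU/GU penalties, computed exactly by dynamic programming.

## Worked example

```r
library(mirtriad)

cfg <- sim_config(seed = 7, n_mirna_probes = 40, n_mrna_probes = 80,
                  n_planted_pairs = 30, n_de_mirna = 10, n_de_mrna = 20,
                  reg_strength = 0.9, pheno_link_strength = 0.9)
b <- generate_dataset(cfg)

de <- select_de(anova_fixed_effect(b$mirna, b$samples), 0.05, 0.2)
targets <- predict_targets(b$mirna_sequences, b$transcripts)
mp <- correlate_with_phenotypes(b$mirna, b$phenotypes)
gp <- correlate_with_phenotypes(b$mrna, b$phenotypes)
mg <- correlate_all(b$mirna, b$mrna, family_fdr = FALSE)
mmap <- setNames(b$mirna_annotation$mature_name, b$mirna_annotation$probe_id)
tri <- build_triads(mp$results, gp$results, mg, targets, mirna_map = mmap)
head(top_pairs_per_trait(tri, n = 10)[, c("mature_name", "gene_id", "trait",
                                          "mirna_gene_r", "mirna_gene_p")], 5)
```

```
DE miRNA probes: 11
predicted target pairs: 135
triads: 88 over 19 traits
  mature_name  gene_id    trait mirna_gene_r mirna_gene_p
1 ssc-miR-129 GENE0058      ADP       -0.930     2.90e-09
2 ssc-miR-116 GENE0035      AMP       -0.950     1.47e-10
3 ssc-miR-108 GENE0037      ATP       -0.963     9.57e-12
4 ssc-miR-109 GENE0072 ComplexI       -0.975     3.19e-13
5 ssc-miR-113 GENE0015 ComplexI       -0.952     1.04e-10
planted pairs recovered: 30/30
```

Each row is a candidate regulation: the miRNA and gene correlate strongly
and negatively (r ≈ −0.93 to −0.98, tiny p), both correlate with the named
trait, and the gene carries a predicted binding site for that miRNA. On
this synthetic run all 30 planted miRNA→gene→trait chains are recovered.

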