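---
title: "Integrating miRNA, mRNA and muscle phenotypes: models and design"
author: "mirtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating miRNA, mRNA and muscle phenotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtriad)
```

## The problem

MicroRNAs tune muscle energy metabolism by destabilising or repressing
their target mRNAs. In a two-breed pig design — one breed with more
slow-twitch oxidative muscle, one leaner and more glycolytic — differences
in miRNA expression, mRNA expression and a panel of 19 physiological
traits (fiber-type percentages, mitochondrial respiration states,
metabolic enzyme activities, adenine nucleotide concentrations) can be
linked into regulatory networks: a miRNA that is higher in one breed,
negatively correlated with a predicted target gene, with both molecules
correlated to the same trait, is a candidate regulator of that trait.

`mirtriad` implements this integration as a reusable, fully tested
pipeline over five analysis stages plus a synthetic-study generator, so
that every stage can be validated against planted ground truth without any
external data download.

## Models and procedures

### Probe filtering

Array probes are kept when their detection ("present") call frequency
reaches at least 70% of samples *within each breed* (inclusive threshold;
`presence_filter()`), and when the annotated probe sequence is shorter
than 30 nt (`length_filter()`, separating mature miRNAs from hairpin
precursors). The "within each breed" sentence is ambiguous between a
conjunctive and disjunctive reading; we default to the conjunctive
`all_groups` rule and expose `any_group` as an explicit option, since the
correct reading is not recoverable from the study description.

### Differential expression

Each probe is tested with a one-way fixed-effect ANOVA on breed
(`anova_fixed_effect()`): \(F = MS_{between}/MS_{within}\) with
\((g-1, n-g)\) degrees of freedom; with two groups this is exactly the
squared pooled *t* statistic, which the tests verify. Sex is *not* in the
default model — only breed is declared a fixed effect — but an additive
covariate switch exists. Least-squares means reduce to group means in the
balanced one-factor default. Multiple testing uses Benjamini–Hochberg
step-up FDR (`bh_fdr()`, delegating to `stats::p.adjust` and validated
against a brute-force min-over-tails oracle). Fold changes are reported
as \(2^{|\Delta \log_2|}\) with the direction carried separately, so that
values are always at least 1. Selection uses strict inequalities
(p < 0.05 together with FDR < 0.2 for miRNA probes, FDR < 0.05 for mRNA
probes, both configurable), and probe-level calls are collapsed to unique
mature miRNA names per direction (`collapse_to_mature()`), flagging
matures whose probes disagree in direction.

### Target prediction

Two independent evidence routes, combined by union (default) or
intersection (`predict_targets()`):

* **Seed matching** (`find_seed_matches()`): exact Watson–Crick reverse
  complements of the miRNA seed (positions 2–8 from the 5' end) are
  located in the 5'UTR, CDS and 3'UTR — all three regions are scanned
  because coding-region and 5'UTR sites are common enough to matter for
  sensitivity. Sites are classified 6mer (positions 2–7), 7mer-m8 (2–8),
  7mer-A1 (2–7 plus an A opposite position 1) or 8mer, reporting the
  strongest classification per locus. G:U pairs are not accepted in the
  seed.
* **Duplex minimum free energy** (`duplex_mfe()`, `scan_duplex()`): a
  dynamic program over intermolecular base pairs only (no intramolecular
  structure, no pseudoknots). Consecutive pairs contribute
  nearest-neighbor doublet stacking terms; bulge/interior loops are
  allowed up to 4 unpaired nucleotides per side; a duplex initiation term
  and AU/GU terminal penalties complete the model. A hit is evidence when
  its energy is at or below −25 kcal/mol, and only the single best hit
  per transcript is retained (ties broken by smaller target start, then
  longer helix, for determinism). Long targets are scanned in 60-nt
  windows with 20-nt steps — the window comfortably exceeds any plausible
  site span while bounding the DP cost.

The energy table (`duplex_params()`) uses the standard Watson–Crick RNA
nearest-neighbor stacking values; G:U wobble doublets are interpolated
from their two Watson–Crick substitutions and damped, and loop penalties
are positive constants by size. The exact parameterisation is deliberately
not the contract: the table ships as a plain TSV and is swappable, and
what the test suite guarantees is that the dynamic program equals
exhaustive enumeration over all valid pairing sets under *whatever* table
is loaded (500 random sequence pairs of combined length ≤ 16, plus an
energy-monotonicity property). No p-value model, conservation filter or
context scoring is attached to predictions.

### Correlation screening

All correlations are Pearson product-moment coefficients on
pairwise-complete observations with the per-pair sample count carried
explicitly (`correlate_all()`, `correlate_with_phenotypes()`). P-values
use the *t* transform \(t = r\sqrt{n-2}/\sqrt{1-r^2}\) with \(n-2\)
degrees of freedom, two-sided; at n = 20 this reproduces published-style
printed values (e.g. r = 0.543 → p = 0.0134, r = 0.6833 → p = 0.0009) to
their printed rounding, and agrees with permutation p-values within
Monte-Carlo error. BH q-values are computed over a declared family (the
full miRNA × mRNA grid for the integration stage). Phenotype screening
keeps both correlation signs and summarises probes significant for at
least one of the 19 traits at raw p < 0.05. qPCR concordance correlates
linear-scale \(2^{-\Delta Ct}\) (ΔCt against the arithmetic mean of two
reference-gene Ct values, equivalent to a geometric mean of linear-scale
levels) with the array's log2 signal.

### Network integration

`integrate_de_pairs()` keeps (miRNA, mRNA) pairs that are negatively
correlated at p < 0.05 *and* FDR < 0.05 within the DE × DE family and
carry target-prediction evidence, reporting pair/gene/mature counts.
`build_triads()` forms (miRNA, gene, trait) records when (1) both
molecules correlate with the trait at p < 0.05, (2) the two molecules
correlate negatively at p < 0.05, and (3) the gene is a predicted target;
the phenotype stage deliberately uses raw p-values, mirroring the
per-trait reporting convention, and traits are treated independently with
no multivariate adjustment. The "top ten pairs per trait" report
(`top_pairs_per_trait()`) needs a rank key that the study description
does not state; we rank by ascending miRNA–gene correlation p, ties by
|r| descending, then lexicographic ids, and record the key in the output.
`crosslist_correlation()` computes the complete grid between two gene
panels (e.g. mitochondria-related vs ubiquitin–proteasome-system genes)
with p < 0.05 flags. Networks export to GraphML (attribute-preserving
round trip via igraph) or SIF, with node type (miRNA/gene/trait) and
breed-direction attributes rather than colors.

### Enrichment

`fisher_enrichment()` performs one-sided (over-representation)
hypergeometric tests of a query gene list against user-supplied GMT gene
sets, with the universe defaulting to the measured (filtered) genes and
BH correction across sets. This is a generic stand-in for proprietary
pathway knowledge bases; no specific pathway claims are made or tested.

## The synthetic study generator

`generate_dataset()` emulates the study conditions: two breeds × 10
samples, probe-level log2 intensities with Gaussian noise (the pipeline
consumes post-normalisation values, so normalisation itself is not
simulated), planted breed effects of `effect_size_log2` (default 1 log2
unit, residual SD 0.5), independent per-probe×sample presence calls
(DABG internals are out of scope), and 19 standardized traits named
after the real panel. The trait distributions and units of the real
study are not modelled — synthetic traits are z-scores by construction,
which is sufficient for correlation-based inference and avoids
fabricating scales.

Planted regulations tie the layers together: each planted (miRNA, gene)
pair receives an extended complementary site (reverse complement of
miRNA positions 2–19 plus an A anchor, so both the seed and the energy
route detect it) written into a randomly chosen region (3'UTR with
probability 0.6, CDS 0.3, 5'UTR 0.1, falling back to the 3'UTR when the
region is too short), and an expression coupling in which the miRNA
explains `reg_strength` of the target's variance with negative sign
(expected correlation \(-\sqrt{reg\_strength}\)). Planted genes drive
traits round-robin; per-trait noise is calibrated so a single driver
correlates approximately `pheno_link_strength` with its trait (when two
chains share a trait the achievable correlation is capped at
\(1/\sqrt{2}\), which still clears the p < 0.05 screening threshold by a
wide margin at n = 20). All randomness flows from one seeded stream with
a fixed draw order, so identical configurations produce byte-identical
bundles.

What passing tests on this generator do *not* show: real arrays have
correlated probe noise, batch effects, non-Gaussian tails and
cross-hybridisation, none of which are simulated; recovery rates on
synthetic data are therefore an upper bound on real-data performance,
and the null-calibration checks validate the statistics, not the
biology.

## Numerical choices and degenerate inputs

* Zero within-group variance with zero between-group difference yields
  F = 0, p = 1; with a nonzero difference, F = Inf, p = 0.
* Constant vectors make a Pearson correlation undefined; such pairs are
  flagged and excluded downstream rather than silently zeroed. |r| = 1
  reports p = 0.
* Coordinates are 0-based half-open internally; sequence positions in
  biological numbering (seed positions 2–8) follow the field convention.
* DNA input is transcribed (T→U) on read; any other letter is an error.
* Duplex ties are broken deterministically (target start, then helix
  length); sequences with no pairable bases report energy `Inf` and no
  hit.
* Strict inequalities everywhere a threshold is written as "< x".

## Problem sizes

The test suite and the acceptance script run entirely on generated data
at desk scale, chosen to keep each check sharp but quick: the pair-count
identity uses the real study's 58 × 2345 probe geometry; null
calibration uses 2000 probes × 20 samples; the end-to-end recovery runs
30 planted chains across 40 miRNA / 80 mRNA probes for 5 seeds; oracle
suites use 500 (duplex), 1000 (BH) and all-N ≤ 30 (Fisher) cases.

## Known limitations

* The duplex energy table is an approximate nearest-neighbor
  parameterisation, not a full Turner set; absolute energies are
  comparable to, but not identical with, RNAhybrid's.
* No conservation, accessibility or context scoring in target
  prediction; expect lower specificity than modern TargetScan on real
  genomes.
* The fixed-effect model covers one factor plus an optional additive
  covariate; no mixed models or empirical-Bayes moderation.
* Enrichment is plain over-representation; no ranked (GSEA-style)
  statistics.
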