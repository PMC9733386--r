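---
title: "Methods: allele-specific and traditional molecular QTL integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific and traditional molecular QTL integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asqtl)
```

# Overview

`asqtl` nominates putative causal regulatory variants by intersecting four
molecular-QTL analyses run on the same animals: allele-specific binding
(asbQTL) and expression (aseQTL) from phased parental allele counts, and
traditional peak-height (hQTL) and exon-expression (eeQTL) association from
count phenotypes. The two families are statistically complementary: the
allele-specific tests compare the two haplotypes *within* heterozygous
individuals (immune to between-individual confounding, but blind to trans
effects), while the mixed-model association compares individuals (sensitive
to any additive effect, but exposed to population structure, which the
polygenic term absorbs). A variant supported by both, located inside the
peak it regulates, and concordant in direction across all four analyses, is
a strong causal candidate.

This vignette records the models, the parameters that matter, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one reading was defensible.

# Phasing and allele counts

Parental origin is assigned from sire genotypes: a homozygous sire fixes the
paternal allele; a heterozygous sire leaves the site ambiguous, and the
orientation of the *nearest upstream resolved site on the same chromosome*
is carried forward through the offspring's input phasing. We deliberately
exclude rather than guess at chromosome starts (no resolved upstream site):
those entries are flagged `unphased` and dropped downstream, as are entries
incompatible with Mendelian transmission.

Per feature and animal, maternal/paternal read counts are summed over the
animal's heterozygous, phased sites in the feature. Two exclusions apply:
animals homozygous at every site (uninformative), and heterozygous sites
with monoallelic reads — one parental count zero while the other is positive
— which indicate imputation error. No minimum-depth threshold is imposed
beyond that rule.

Pooling sites into one phenotype per feature assumes the sites share a
maternal:paternal ratio; the s×2 G-test checks this per feature, with
`G = 2(Σ n_ij ln n_ij + n.. ln n.. − Σ n._j ln n._j − Σ n_i. ln n_i.)` and
`0·ln 0 ≡ 0`. **Degrees of freedom** are `s − 1` (the standard independence
df for an s×2 table); a single-site table is degenerate (G = 0, df = 0,
p = 1, flagged). Floating-point residue below 1e-9 is snapped to zero so
identical ratios report p = 1 exactly.

# The two-stage allele-specific scan

All SNPs within 1 Mb of the feature midpoint (midpoint =
`floor((start + end)/2)` in the package's 0-based half-open coordinates)
are candidate driver SNPs (dSNPs).

**First test.** Over dSNP-heterozygous animals, with `A` the reads on the
alternate-carrying haplotype and `T` all reads,
`Z = (A/T − 0.5)·√(4T)` is the score statistic of a binomial(T, ½) test and
approximately standard normal. We use two-sided p-values (no directional
prior on imbalance); the stage-two gate is p < 0.001 and final significance
p < 0.0001 in *both* tests. The normal approximation deviates from the
exact binomial p only by binomial discreteness (at most roughly the central
point mass, √(2/πT)), which is negligible in the decision-relevant tail at
the depths involved.

**Second test.** `Y_i = ln((maternal_i + 10)/(paternal_i + 10))` on
`X_i ∈ {0, +1, −1}` by ordinary least squares, one observation per animal
(the summed feature counts — matching the pooling above), two-sided t-test
on the slope. The +10 pseudocount bounds the log-ratio for shallow counts.
Animals with unphased dSNP genotypes are dropped from both tests; fits with
fewer than 3 animals, a constant X, or zero residual variance are flagged
degenerate rather than given a p-value. No covariates enter the second test
(batch affects both alleles of an animal equally and cancels from the
within-animal ratio).

# Traditional QTL mapping

**Peak phenotype.** Counts are normalised by the per-animal mean across
peaks, log-transformed (`ln(x+1)`), and input-corrected per peak by OLS of
peak on input; the residual vector is the phenotype, so it is exactly
orthogonal to the log input and sums to zero. QC first removes peaks below
the 1% quantile of per-peak total counts — the empirical
linear-interpolation quantile applied to totals across animals, a
convention we fixed because "peak read count" admits several aggregations —
and peaks whose total input exceeds 5× the mean (reference artefacts).

**Expression phenotype.** Exons with median count < 5 are excluded;
remaining counts are divided by median-of-ratios size factors and
transformed `log2(x/sf + 1)`. This is a deliberately simple, fully-defined
variance-stabilising transform: it removes depth composition bias and
compresses the count-variance relationship, which is what the downstream
linear model needs, at the cost of not flattening the variance of
low-count exons as aggressively as a fitted dispersion-based
transformation would. Batch is then removed per exon by centring each
batch at the grand mean (adjustment after transformation; single-animal
batches are left uncentred with a warning).

**Outliers.** A single PCA pass removes animals more than 4 SD from the
mean on any of the first 7 components (capped at the available rank, with a
warning). The 4-SD tail is ~6e-5 per test, so clean data lose essentially
no animals.

**Mixed model.** `y = Xc + g·β + u + e` with `cov(u) = σ²_g K`, where K is
the first-VanRaden GRM (`W W′/m`, columns standardised by `√(2p(1−p))`,
monomorphic SNPs skipped) built from all chromosomes except the feature's
(LOCO, avoiding double-fitting the tested variant). Variance components are
estimated by REML through a single spectral decomposition of K
(EMMA-style) — the contract is the model, not any particular solver — and
the decomposition is shared by all features on the same chromosome, which
is algebraically identical to refitting per phenotype. Each candidate SNP
then gets a generalised-least-squares β, its standard error, and a
two-sided t-test. Numerical choices: eigenvalues clamped at zero; a 1e-6
ridge if the GRM is indefinite; the REML ratio profile optimised on
log(σ²_g/σ²_e) over [1e-6, 1e6], with the lower boundary treated as σ²_g =
0 (the model then collapses to OLS). ChIP batch enters as a one-hot
covariate with reference level; expression phenotypes are already
batch-centred and get none. Dosage is the alternate-allele count, so β's
sign is directly comparable with the allele-specific slope (alternate
maternal coded +1).

# Integration

Overlap between result sets uses the sample cross-product odds ratio
`ad/bc` on the 2×2 table of tested features; the source tables' estimator
is unstated, and the cross-product reproduces the printed values at printed
rounding for nine of ten rows (the tenth differs by 0.006). Enrichment of
QTL under peaks is `(C/A)/(B/D)` with peak intervals merged first;
"positions" default to tested SNP sites, with a flag for the
base-pair convention for A and D. Direction comparison maps both effect
estimates onto the alternate-allele axis before comparing signs;
zero-effect entries are excluded and counted. Candidate causal variants
must have p < 0.0001 in the hQTL and eeQTL scans and in the *first*
allele-specific test of both scans, lie inside their peak, and agree in
direction in all four analyses; each variant's four p-values are combined
by summing their upper-tail χ²(1) quantiles against χ²(4), and only the
lowest combined p per peak–exon pair is kept (ties broken by lowest genomic
position, deterministically, and logged).

# Motif discovery

Variants entering motif discovery are asbQTL inside their peak below a
mark-specific threshold (1e-8 H3K4Me1, 1e-7 H3K4Me3, 1e-6 H3K27ac — the
last exempt from the in-peak rule because too few such sites exist) and
aseQTL within 10 kb of the target's start below 1e-15. Thresholding uses
the first-test p, for consistency with the causal-variant filter, which is
explicitly tied to the first test; the positive (binding/expression-
increasing) allele is read from the sign of Z.

For each variant the 21 bp reference window (SNP ± 10 bp) and its reverse
complement are extracted (windows at contig edges or containing non-ACGT
bases are skipped and logged; a sequence may co-cluster with its own
reverse complement — no dedup rule is imposed). Complete-linkage
clustering on Levenshtein distances over the central nine bases is cut at
height 3, so every intra-cluster pair differs by at most three edits;
clusters under 10 members are discarded. Cluster PFMs are rendered as a
consensus: flanks are trimmed while the column's *information content*
(2 − entropy) is below 0.2 bits — the coherent reading of a rule whose
literal text ("entropy below 0.2") would delete the most conserved columns;
the literal behaviour is retained behind `literal_entropy = TRUE`. Retained
columns accumulate bases by descending frequency (ties in fixed A, C, G, T
order) until the running sum strictly exceeds 0.85, emitting a base or a
bracketed class. Genomic enrichment is non-overlapping forward-strand regex
matches (reverse complements already entered the pool) over the expected
count `Π(Σ included base frequencies) × total length`; total raw length is
used rather than length − width + 1, a negligible difference at genome
scale. Default background frequencies are A = T = 0.291, C = G = 0.209
(bovine autosomal composition), recomputable from any genome with
`genome_base_freqs()`. Allele skew per cluster is the multinomial LLR
against 25% each, with an exact full-enumeration p for N ≤ 20 and a seeded
1e5-draw Monte-Carlo p above (the estimator `(s+1)/(B+1)` keeps p in
(0, 1]); the method used is recorded. PFM database matching slides the
shorter matrix ungapped along the longer, scores `2 − Σ|q − t|` per
column-normalised column, and reports `relScore = 100·total/(2·width)` above
90 — a stated emulation contract, since the referenced tool's internal
scoring is not published.

# The synthetic-data generator

The generator produces every input the pipeline consumes with known ground
truth: phased trios (maternal haplotype from population frequencies,
paternal transmitted from a simulated sire, so Mendelian consistency is
exact by construction), input-phased offspring haplotypes with random
per-chromosome orientation (what a statistical phaser leaves), features
anchored on distinct SNPs so each has an informative site, a truth table of
causal dSNPs (half inside their feature) whose allelic log-odds effect and
additive log-level effect share one sign — one cis mechanism — and, for
half the causal peaks, one or two nearby exons driven by the same variant
so peak–exon links and four-way candidates exist by construction.

Counts follow the field's standard noise models: per-site depths and
feature totals are negative-binomial (dispersion 0.2 by default, Poisson at
0), allelic splits are beta-binomial around `plogis(X·effect)` (intra-class
ρ = 0.02 by default), totals carry batch effects (SD 0.15 on the log scale)
and a polygenic term built from genome-wide small SNP effects (variance
0.05), and input counts are genotype-independent. Defaults — 200 animals, 2
chromosomes × 3 Mb × 400 SNPs, MAF uniform on (0.1, 0.5), mean depth 50,
60 + 60 features of 0.3–2 kb, 30% causal with allelic effects 1.5–2.5
log-odds units and level effects 0.3–0.6 per allele — are chosen so that a
mid-sized cohort at moderate depth is realistic and cis effects of the size
the method targets are comfortably but not trivially detectable.

What the generator does *not* emulate: linkage disequilibrium (SNPs are
independent, so there is no LD shadow around causal variants — power
estimates are therefore per-variant, not per-locus), read-level artefacts
(no FASTQ, no mapping or reference bias; the upstream masked-genome step is
out of scope), phase-set switch errors, imprinting, and trans effects.
Passing tests consequently certify the statistics and their wiring, not
robustness to alignment artefacts or LD-confounded fine-mapping.

# Problem sizes and reproducibility

All randomness flows from one master seed through fixed per-generator
offsets, so identical configurations are byte-identical. The test suite
runs the full pipeline at 200 animals × 330 features (about 100 causal) for
parameter recovery, 2,000 null feature–dSNP pairs for first-test
calibration, 2,000 null tables for G-test type-I error, and 30 planted + 100
background variants for motif recovery — sizes at which every targeted
property is measurable in minutes on a laptop. The same computations back
`scripts/acceptance.R`.

# Known limitations

* The second allele-specific test fits no covariates; a batch that altered
  the two alleles differentially (not expected for a within-animal ratio)
  would go unmodelled.
* The consensus information-content trim at 0.2 bits is noisy for clusters
  near the 10-member minimum; an occasional near-random flank column
  survives, widening the regex slightly.
* The OR is the unconditional cross-product ratio; conditional-MLE
  estimators can differ in the third significant digit.
* The variance-stabilising stand-in under-corrects very low-count exons
  relative to dispersion-based transforms.
* PFM similarity is an ungapped emulation with a stated scoring contract,
  not a reimplementation of any external tool.
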