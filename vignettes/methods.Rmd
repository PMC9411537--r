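---
title: "Methods: models, estimators and design choices in pangopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in pangopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangopop)
```

pangopop is a desk-scale re-implementation of the population-genomic
toolkit used to assess small, fragmented populations of threatened
species — the motivating case being Chinese pangolin resequencing panels
split into three populations (here labelled CPA, CPB, CPC) with a
congeneric outgroup. This vignette explains the statistical models the
package implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the underlying methods literature leaves choices open.

## Input model and site filtering

All statistics operate on a `geno_matrix`: biallelic SNP sites by
diploid samples, calls stored as alt-allele dosages (0/1/2, `NA`
missing), with optional phased haplotypes. Multi-allelic records and
indels are dropped at VCF import rather than decomposed, because every
estimator downstream assumes two alleles.

Site filters mirror common post-calling practice for fragmented
assemblies: SNPs on scaffolds shorter than 100 kb are removed (short
scaffolds are enriched for assembly artefacts), and analyses can be run
on three nested SNP sets — all SNPs, minor allele frequency strictly
greater than 5%, and strictly greater than 20% — with MAF computed on
the pooled study panel excluding the outgroup. The inequality is strict
("larger than"), and thresholds sit on the MAF scale, so a site at
exactly 5% is removed from the second set.

Ancestral states come from the outgroup: a site is polarized only when
every non-missing outgroup call is homozygous for the same allele;
heterozygous, discordant or absent outgroup calls leave the site
`unknown`, and unknown sites are excluded from every derived-allele
computation (D, F3 polarization, load, iHS) rather than imputed from the
study-panel majority. This is deliberately conservative: mispolarized
sites bias D and load counts in ways that are hard to diagnose, whereas
excluded sites only cost precision.

## Differentiation: Weir–Cockerham FST, F3, D

`wc_fst()` implements the Weir & Cockerham (1984) variance components
a (among populations), b (among individuals within populations) and c
(within individuals) per site, from sample sizes, allele frequencies and
observed heterozygote fractions. The genome-wide estimate is the ratio
of sums `sum(a) / sum(a + b + c)`; negative per-site components are kept
in the sums. Sites need at least two called diploids per population and
pooled polymorphism to contribute.

`f3(target; s1, s2)` is the mean over sites of `(x - a)(x - b)` with the
finite-sample correction `x(1 - x) / (n_hap - 1)` subtracted for the
target's binomial sampling noise; a significantly negative value
(Z < -3) says the target's frequencies sit between the sources, i.e. it
is admixed. F3 is reported unnormalized; the heterozygosity-normalized
variant is out of scope.

`d_statistic()` is the frequency-based ABBA–BABA test on the topology
((A, B), (X, outgroup)): with derived frequencies pA, pB, pX per
polarized site, `ABBA = (1 - pA) pB pX` and `BABA = pA (1 - pB) pX`
accumulate, and `D = (ABBA - BABA) / (ABBA + BABA)`. The outgroup enters
only as polarizer (its derived frequency is 0 by construction).

Standard errors for D and F3 use a weighted block jackknife (Busing et
al. 1999) over contiguous genomic blocks, weights equal to the per-block
informative mass; with equal weights it reduces to the ordinary
delete-one jackknife, which the tests assert. The block length defaults
to 5 Mb — the source analyses do not state theirs, and 5 Mb comfortably
exceeds linkage disequilibrium range in a mammal, making block estimates
approximately independent. `|Z| > 3` flags significance, matching the
screening rule used with these statistics. When every block gives the
same estimate the jackknife variance is 0; the Z is then reported as an
infinite sentinel with a warning rather than silently dropped.

## Diversity: He, pi, PCA

Per-sample heterozygosity He is a ratio of heterozygous genotypes to a
denominator that the caller chooses explicitly: callable sites (default;
robust to missingness differences between SNP sets) or total genome
length (a per-bp rate). Reports always name the denominator, because the
two scales differ by orders of magnitude and published values rarely say
which was used.

Windowed nucleotide diversity uses the unbiased per-site estimator
`2 p (1 - p) n / (n - 1)` (n = called alleles), summed per window and
divided by window length; windows tile scaffolds left to right and the
last partial window is kept with its own length. PCA uses Patterson
normalization — dosages centred by `2p` and scaled by `sqrt(p(1 - p))`,
missing values mean-imputed, monomorphic sites dropped — and returns
eigenvector coordinates scaled by the root eigenvalues so that distances
in the retained subspace approximate those of the normalized data.

## Runs of homozygosity and inbreeding age

`detect_roh()` is a PLINK-style scan. Parameters (defaults in
parentheses): `window_snps` (50), `het_allowance` (1 heterozygote per
window), `missing_allowance` (5), `hit_threshold` (0.05, the fraction of
covering windows that must be homozygous for a SNP to count as in-ROH),
`min_snps` (50), `max_gap_kb` (100) and `min_length_kb` (100, floor
enforced). Only segments of at least 100 kb are ever emitted, split into
medium (100 kb–1 Mb) and long (> 1 Mb) classes; F_ROH divides summed
segment length by total genome length, matching the genome-fraction
phrasing such values are reported with.

The detector's spatial resolution is the physical span of its 50-SNP
window. Recovery tests therefore use panels at 2 SNPs/kb or more, and
the "an 80 kb tract is never called" check runs at 8 SNPs/kb: at sparser
densities a PLINK-style scan legitimately pads a true tract by up to
roughly a window span per side, which at 1 SNP/kb is ~50 kb and would
cross the 100 kb floor. Real resequencing panels in this setting carry
~15 SNPs/kb, so the test densities are the conservative side of
realistic.

The expected age of the inbreeding event behind a tract of genetic
length L cM is `g = 100 / (2 L)` generations. The printed form of this
formula is sometimes ambiguous ("100/2 * length"); the reciprocal form
is the correct one — the literal product would make older events produce
longer tracts, contradicting both recombination theory and the
accompanying "< 50 years for > 1 Mb" interpretation. Physical length
converts to genetic length with a flat 1 cM/Mb map and a 1-year
generation time by default, so a 1 Mb ROH dates to 50 generations = 50
years.

## Mutational load and translocation risk

Severity classes: LoF = splice donor, splice acceptor, stop gained;
missense changes are scored with the Grantham (1974) amino-acid distance
and called deleterious at GS >= 150, boundary inclusive. The canonical
score table is the published integer matrix — the same table variant
annotators ship — while `grantham_from_properties()` recomputes the
distance from the composition/polarity/volume property triples
(alpha = 1.833, beta = 0.1018, gamma = 0.000399, mean normalized to
100). The two routes agree exactly at the extremes (Leu–Ile 5, Cys–Trp
215) and within one unit almost everywhere, but the published table is
not exactly regenerable from the formula: 41 of 190 pairs differ by one
unit and Asp–Trp by ten (printed 181, formula 191), a long-known quirk
of the original publication. The package keeps the published values as
canonical because classification thresholds in the literature were set
against them.

Load accounting counts, per individual, sites carrying at least one
derived allele, split by category and zygosity. The population zygosity
ratio pools site counts across members — `sum(hom) / sum(hom + het)` —
rather than averaging per-individual ratios, matching how single
population-level values are reported; the per-individual variant is
available for comparison. A zero denominator yields `NA` with a warning,
never 0.

`predict_translocation_lof()` asks, for each donor individual, how many
LoF sites would be new to a receiver population: the donor carries at
least one derived allele and the derived allele is absent from every
called receiver genotype. Missing receiver genotypes do not veto
novelty, making the count an upper-bound-style prediction; the rule is
recorded in the output because the underlying analyses do not define
theirs. Direction matters, and adding derived-LoF carriers to the
receiver can only decrease counts (an invariant the tests assert).

## Selection scans: EHH, iHS, region screening

EHH at marker m is the probability that two random carrier haplotypes of
the core allele are identical at every marker from the core to m,
computed as `sum C(k_g, 2) / C(K, 2)` over haplotype groups. iHH
integrates EHH against genetic distance (trapezoid rule, cM units from
the flat 1 cM/Mb map) outward in both directions, stopping at the EHH
floor of 0.05; unstandardized iHS is `ln(iHH_A / iHH_D)`, standardized
within 20 equal-count derived-frequency bins. Core sites need derived
frequency in [0.05, 0.95] and at least two carrier haplotypes per
allele. Marker gaps above 200 kb terminate a curve — a guard against
unassembled regions masquerading as haplotype homozygosity. Sites where
either integral is zero are flagged invalid rather than mapped to
infinite scores.

Candidate sites are the top 0.1% of |standardized iHS|, ties included.
Region screening reproduces the three standard methods — consecutive
50-SNP blocks, 100 kb windows stepped 50 kb, and merged 5 kb flanks
around candidates — scores each candidate-containing region by siHS (the
sum of |iHS| over its candidate sites; a signed-sum option exists
because the source convention is ambiguous), keeps the top 10% per
method among candidate-containing regions, and intersects the
overlapping gene sets across methods. Both "top 10% within
candidate-containing regions" and the absolute-value siHS are recorded
choices where the methods literature is silent.

## The synthetic generator: what it emulates, what it does not

`simulate_panel()` draws per-site ancestral frequencies from a
Beta(0.3, 0.3) truncated to (0.01, 0.99) — chosen to give the strong
excess of rare variants (roughly half of SNPs below 5% MAF) seen in
large resequencing panels — and propagates them down a two-level tree
under the Balding–Nichols model: daughter frequency ~
`Beta(p(1-F)/F, (1-p)(1-F)/F)`. Because the Balding–Nichols F *is* the
among-population correlation the Weir–Cockerham estimator targets,
genome-wide FST between two independently drifted daughters recovers F,
giving closed-form parameter-recovery tests without an external
coalescent simulator. Defaults emulate the study conditions: sample
sizes 11/18/8 plus one outgroup genome, deep/shallow drift 0.5/0.1 (the
regime of published FST values near 0.54 and 0.10), 2% missingness, a
coding-enriched consequence mix (10% synonymous, 8% missense, 1% LoF)
with 20% of missense draws deleterious so load tables have usable counts
at 2 × 10^4 sites.

Phased panels draw haplotype alleles independently per site (linkage
equilibrium); a sweep is constructed generatively, not by forward
simulation: haplotypes carrying the derived core allele are copies of
one founder over a tract (default 500 kb) with sparse private mutations.
This creates exactly the EHH contrast iHS measures, with a known core.

Features of real data deliberately not emulated: linkage disequilibrium
outside sweep tracts (so background iHS has no LD noise), selection
against deleterious alleles (expected per-individual derived-allele
counts are invariant under pure drift, so no population can carry
systematically fewer derived LoF alleles — the load asymmetry reported
between real populations reflects demography/selection outside this
model; translocation-count asymmetries here are driven by frequency
divergence alone), sequencing error, and variable recombination.
Passing tests therefore validate estimator correctness and calibration,
not robustness to those real-data features.

One global seed governs all draws; derived analyses seed their own
substreams from it, and the pipeline manifest records every parameter so
a run is reproducible from the manifest alone.

## Problem sizes

Tests and the acceptance script run at 2 × 10^4 sites for
differentiation, load and selection analyses (10 scaffolds of 10 Mb),
4 × 10^4 sites on 20 Mb for ROH recovery (2 SNPs/kb), 1.6 × 10^4 sites
on 2 Mb for the ROH floor check (8 SNPs/kb), 50 replicates of 10^4 sites
for D calibration, and 20 sweep replicates for iHS power — sizes at
which every stochastic check is stable under seed changes while the full
suite completes in a few minutes.

## Known limitations

* The genotype container is dense; panels far beyond ~10^6 sites ×
  hundreds of samples would need a sparse or file-backed backend.
* iHS walks haplotypes in R; scans over tens of millions of sites would
  want a compiled kernel.
* D uses population allele frequencies (as frequency-based
  implementations do), not single pseudo-haploid draws; results on tiny
  samples can differ from draw-based tools.
* The translocation prediction ignores missing receiver genotypes when
  declaring novelty; with heavy missingness it overpredicts.
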