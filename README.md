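# pangopop

Population genomics for small, fragmented populations of threatened
species — built around the analyses used to assess Chinese pangolin
(*Manis pentadactyla*) resequencing panels, and usable for any diploid
species with a multi-sample VCF, a population map and an outgroup.

Conservation genomics of such panels keeps asking the same questions:
how differentiated are the remnant populations, how inbred are the
individuals, how much deleterious variation does each population carry,
and what would a genetic-rescue translocation move between them?
pangopop answers them with the field's standard statistics, implemented
from their defining formulas and verified against brute-force oracles
and parameter-recovery simulations:

* **Diversity** — per-sample heterozygosity He, windowed nucleotide
  diversity π (unbiased `2p(1−p)·n/(n−1)` per site), genotype PCA with
  Patterson normalization.
* **Differentiation & gene flow** — Weir–Cockerham FST
  (`Σa / Σ(a+b+c)`, ratio of sums), the three-population statistic
  F3(target; s1, s2) = E[(x−a)(x−b)] with finite-sample correction, and
  the ABBA–BABA D statistic
  `D = (ABBA − BABA)/(ABBA + BABA)` on outgroup-polarized frequencies;
  D and F3 carry weighted block-jackknife standard errors with the
  `|Z| > 3` significance rule.
* **Inbreeding** — PLINK-style runs of homozygosity (sliding 50-SNP
  windows), F_ROH by size class (medium 100 kb–1 Mb, long > 1 Mb), and
  the expected inbreeding age `g = 100/(2·L_cM)` under a 1 cM/Mb map —
  a 1 Mb ROH dates to 50 generations.
* **Mutational load** — outgroup-polarized derived-allele accounting:
  LoF (splice donor/acceptor, stop gained), Grantham-score missense
  classification (deleterious at GS ≥ 150), pooled zygosity ratios
  `hom/(hom+het)`, and per-donor predictions of LoF variants a
  translocation would newly introduce into a receiver population.
* **Selection scans** — EHH and iHS (`ln(iHH_A/iHH_D)`, standardized in
  derived-frequency bins), top-0.1% candidate sites, and the
  three-method candidate-region screen (consecutive 50-SNP blocks,
  100 kb/50 kb windows, merged 5 kb flanks) with siHS top-10% filtering
  and cross-method gene intersection.
* **Synthetic panels with known truth** — a Balding–Nichols generator
  for the three-population topology (deep + shallow splits, optional
  admixture pulse, injected ROH tracts, generative sweeps), so every
  estimator has a parameter-recovery test.

Everything takes tidy inputs and returns tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a study-like panel — three populations (deep split ≈ 0.5,
shallow split ≈ 0.1, sample sizes 11/18/8) plus an outgroup — then run
the differentiation and load analyses:

```r
library(pangopop)

cfg   <- sim_config(seed = 42, n_sites = 20000)
panel <- simulate_panel(cfg)
gm    <- polarize_by_outgroup(panel$genotypes, panel$populations)
pm    <- panel$populations

fst_matrix(gm, pm)
#>   pop_a pop_b   fst n_sites
#> 1 CPA   CPB   0.102    8469
#> 2 CPA   CPC   0.533   11449
#> 3 CPB   CPC   0.534   11664
```

The recovered FST values match the simulated drift: ≈ 0.10 across the
shallow split and ≈ 0.53 across the deep one — the regime where one
pair of populations is differentiated at a population level and the
other at a subspecies level. With no simulated gene flow, D is
consistent with zero:

```r
glance(d_statistic(gm, pm, "CPA", "CPB", "CPC", cfg$layout))
#>   A     B     X         D  abba  baba      se     Z n_blocks significant
#> 1 CPA   CPB   CPC 0.00187  634.  631. 0.00960 0.195       20 FALSE
```

Load accounting and the translocation prediction (mean per-donor LoF
variants newly introduced into the receiver):

```r
zygosity_ratio(derived_load_counts(gm, pm), "lof")
#>   population category n_hom n_het ratio
#> 1 all        lof       2937   976 0.751

translocation_matrix(gm, pm)
#>   donor receiver   min   max  mean
#> 1 CPA   CPB          0     3  1.09
#> 2 CPA   CPC          7    11 10
#> 3 CPB   CPA          0     2  1
#> 4 CPB   CPC          9    14 11
#> 5 CPC   CPA          6    11  8.12
#> 6 CPC   CPB          6    10  8.25
```

Moves across the deep split would introduce ~8–11 new LoF variants per
donor against ~1 within the shallow pair — the quantitative argument
for caution in rescue planning. Finally, inbreeding ages from ROH
length:

```r
generations_from_roh(c(5e5, 1e6, 2e6), cfg$layout)
#>   length_bp length_cm generations years
#> 1    500000       0.5         100   100
#> 2   1000000       1.0          50    50
#> 3   2000000       2.0          25    25
```

Every ROH longer than 1 Mb reflects inbreeding within the last 50 years
at a 1-year generation time. The full pipeline (`run_pipeline()`, or
the CLI at `inst/cli/pangopop.R`) chains these stages from a YAML
config and writes TSV tables plus a reproducibility manifest.

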