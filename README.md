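# ardi: gene-gene interaction testing for case-control GWAS

`ardi` is an R toolkit for genome-wide searches for pairwise gene-gene
(GxG) interaction in case-control genetic association studies, built for
multi-study consortium data. Its core is the **Average Risk Due to
Interaction (ARDI)** test: a covariate-adjusted logistic regression

&nbsp;&nbsp;&nbsp;&nbsp;logit P(d = 1) = β₀ + β₁G₁ + β₂G₂ + γ̄·c(G₁)c(G₂) + δ'X

with log-additive main effects on the allele dosages G₁, G₂ ∈ [0, 2] and a
single interaction parameter γ̄ on the product of carrier scores
c(G) = min(G, 1) (or P(G ≥ 1) when genotype probabilities are available).
γ̄ is the averaged deviation of the four non-reference genotype
combinations from the main effects — one degree of freedom where the
unrestricted model spends four, and without the multiplicative model's
assumption that the double-homozygote interaction is four times the
double-heterozygote one on the log scale. Because the main effects use the
same additive coding as a standard marginal scan, screening on marginal
association is independent of the interaction test.

Around that core the package provides:

* per-study logistic fits (IRLS, honest convergence/separation flags,
  optional Firth penalty) for the ARDI, multiplicative, unrestricted
  (4-df LRT) and unrestricted-main ARDI models, plus marginal tests;
* inverse-variance fixed-effect and DerSimonian–Laird random-effects
  meta-analysis with Cochran Q heterogeneity, phase-wise (discovery /
  replication / combined) reporting and forest-plot data;
* the two published search strategies: genome-wide scans against a panel
  of known susceptibility loci, and a two-stage marginal-screen →
  LD-prune → all-pairs scan with Bonferroni accounting;
* genomic-inflation diagnostics (λ, QQ data) with a main-effect
  misspecification guard that recodes a locus to 2-df mains when its
  interaction scan inflates (λ > 1.05);
* two-locus interaction-pattern tables (3×3 joint ORs, stratified and
  carrier-collapsed views, cell-level interaction ORs);
* dosage I/O (VCF with DS/GP via vcfR, plain TSV matrices), allele
  harmonization across studies;
* a simulator for multi-study case-control data under Hardy–Weinberg
  genotypes, configurable LD, two-locus penetrance presets, covariate
  effects and imputation dosage noise.

## Worked example

Simulate a four-study consortium with a planted protective carrier-product
interaction, exp(γ̄) = 0.75, test each study, and meta-analyze:

```r
library(ardi)

specs <- lapply(1:4, function(i)
  sim_study_spec(n_case = 1500, n_control = 1500,
                 phase = if (i <= 3) "phase1" else "phase2"))
model <- penetrance_model("ardi_carrier", gamma = log(0.75),
                          b1 = 0.15, b2 = 0.10)
studies <- simulate_consortium(specs, model, master_seed = 42)

fits <- lapply(studies, gxg_test, snp1 = "snp1", snp2 = "snp2",
               model = "ardi")
fits[[1]]
#> ardi test, study study01: snp1 x snp2
#>   OR = 0.793 (95% CI 0.615-1.023), p = 0.0747
#>   1500 cases / 1500 controls

est <- effect_estimates(fits)
est$phase <- sapply(studies, function(s) s$phase)
phase_meta(est)$combined
#> fixed-effect meta-analysis of 4 studies
#>   OR = 0.781 (95% CI 0.688-0.888), p = 0.000148
#>   Cochran Q = 0.377, P_het = 0.945, tau^2 = 0
```

One study alone is equivocal (OR 0.79, p = 0.07); the inverse-variance
combination of four studies recovers the planted interaction (OR 0.78
against a true 0.75) at p ≈ 1.5×10⁻⁴ with no heterogeneity (P_het = 0.95).

Interaction-pattern arithmetic works directly on reported odds ratios: a
genotype combination with joint OR 0.87 whose stratum main effects are
1.03 and 1.11 carries a cell-level interaction OR of

```r
cell_interaction_or(0.87, 1.03, 1.11)   # 0.87 / (1.03 * 1.11)
#> [1] 0.76
expected_joint_or(1.03, 1.11)           # joint OR expected without interaction
#> [1] 1.14
```

and the multiple-testing accounting for a pruned panel of 163 SNPs is

```r
bonferroni_pairs(163)
#> $n_tests   13203
#> $threshold 3.787018e-06
```

A thin command-line front end over the same functions lives in
`inst/cli/gxg-scan.R` (subcommands `simulate`, `scan-pairs`,
`scan-known-loci`, `qq`).

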