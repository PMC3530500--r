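---
title: "Testing gene-gene interaction with ARDI: models, screening and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene-gene interaction with ARDI: models, screening and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardi)
```

## The problem

Genome-wide association studies test one SNP at a time, but complex-disease
risk plausibly involves interplay between loci. A pairwise gene-gene (GxG)
interaction scan asks whether the joint effect of two SNPs on case-control
status departs from the combination of their marginal effects. Two things
make this hard in practice: the interaction parameterisation (a wrong one
costs power or calibration), and the multiplicity of candidate pairs, which
demands screening strategies whose selection step must not distort the
downstream test.

This package implements one coherent answer for multi-study consortium
data: the Average Risk Due to Interaction (ARDI) test, the surrounding
screening machinery (marginal screen, LD pruning, known-locus scans,
Bonferroni accounting), per-study covariate-adjusted logistic fits combined
by inverse-variance meta-analysis, genomic-inflation diagnostics with a
main-effect misspecification guard, two-locus interaction-pattern tables,
and a simulator that generates multi-study case-control data under
configurable two-locus penetrance models.

## Interaction models

All tests are covariate-adjusted logistic regressions for disease status
$d \in \{0,1\}$ on two SNPs with count-allele dosages $G_1, G_2 \in [0,2]$
and covariates $X$ (age, sex, center indicators, principal components).
With carrier scores $c_j = \min(G_j, 1)$ (or $P(G_j \ge 1)$ when genotype
probabilities are available):

* **ARDI**:
  $\operatorname{logit} P(d{=}1) = \beta_0 + \beta_1 G_1 + \beta_2 G_2 +
  \bar\gamma\, c_1 c_2 + \delta'X$.
  The main effects stay log-additive — the same coding as the marginal
  association test, which is what makes marginal screening independent of
  this interaction test — while the single parameter $\bar\gamma$ is the
  averaged deviation of the four non-reference genotype combinations from
  the mains. One-degree-of-freedom Wald test; the per-study
  $(\hat{\bar\gamma}, \text{SE})$ pair feeds the meta-analysis.
* **Multiplicative**: interaction term $G_1 G_2$ instead of $c_1 c_2$.
  This classic coding assumes the double-homozygote interaction is four
  times the double-heterozygote one on the log scale — a strong assumption
  that ARDI is designed to avoid.
* **Unrestricted**: 2-df indicator mains per SNP plus four free cell
  parameters $\gamma_{jk}$, tested with a likelihood-ratio chi-square on
  (up to) 4 df. Assumption-free but pays for the extra degrees of freedom;
  empty cells drop their parameter, reduce the df and are flagged.
* **ARDI with unrestricted mains** (`ardi_umain`): the single
  carrier-product interaction on top of 2-df mains. Used by the inflation
  guard when additive main-effect coding is rejected by the data.

The carrier-product reading of the ARDI interaction term is consistent
with the published worked examples: collapsing the reported two-locus
pattern table to carrier-by-carrier cells gives
$0.88 / (1.05 \times 1.11) \approx 0.75$, matching the reported ARDI
interaction OR of 0.74 for that pair.

Because the carrier score is asymmetric in the two alleles, ARDI is *not*
invariant under re-declaring which allele is counted; the multiplicative
and marginal tests are (their flipped design spans the same column space).
The test suite verifies both facts numerically. Dosage-only data uses
$\min(d, 1)$ as the carrier score — exact when the minor-homozygote
probability is zero, a bounded approximation otherwise — and genotype
probabilities when the VCF provides `GP`.

## Fitting engine

Fits are maximum likelihood via iteratively reweighted least squares
(log-likelihood tolerance $10^{-8}$, at most 100 iterations). Rank
deficiency, constant outcomes and separation-like solutions (coefficients
beyond $\pm 15$ on the log-odds scale or SEs beyond 50) are reported as
`converged = FALSE` with a diagnostic, and such estimates are excluded from
meta-analysis with a logged count rather than propagated silently. An
optional Firth (Jeffreys-prior) penalty is available for sparse tables; it
is off by default and is never used in the headline analyses.

## Meta-analysis

Per-study estimates are combined with inverse-variance weights
$w_i = 1/\text{SE}_i^2$: $\bar\beta = \sum w_i \beta_i / \sum w_i$,
$\text{SE} = (\sum w_i)^{-1/2}$, 95% CI $\exp(\bar\beta \pm 1.96\,
\text{SE})$. Heterogeneity is Cochran's $Q$ with $k-1$ df; the
random-effects variant is DerSimonian–Laird,
$\tau^2 = \max\{0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\}$. The
heterogeneity p-value is always computed from the fixed-effect $Q$, also
when random-effects results are reported (standard DL practice). Studies
never pool individual-level data: each study is fitted separately (center
indicators within study) and only study-level estimates are combined.
Phase-1 (discovery), phase-2 (replication) and combined results are
reported side by side; advanced-adenoma studies are carried in forest data
but enter the combined analysis only on request. No extra weighting for
imputation quality is applied because dosage uncertainty already inflates
per-study SEs, which inverse-variance weighting down-weights automatically
— a property the test suite checks by injecting increasing dosage noise
and observing a monotonically growing meta SE.

Estimates with SE > 10 on the log-OR scale are excluded as separation
artifacts before combining (guards forest plots and meta results).

## Screening strategies

Two published strategies are implemented.

**Known-locus scan.** Each locus of a fixed panel (14 confirmed
colorectal-cancer risk loci in the shipped panel) is tested genome-wide
against every SNP passing MAF > 0.05 and mean imputation $R^2$ > 0.3.
Discovery-phase interactions with $p < 10^{-6}$ advance to replication;
within an LD cluster of selected interactors ($r^2 > 0.8$) only the most
significant SNP is reported, and SNPs in LD with the locus itself are
excluded as interactors, since testing interaction between two SNPs
carrying the same signal is not meaningful.

**Two-stage all-pairs scan.** A genome-wide marginal scan (additive
coding) keeps SNPs with both fixed- and random-effects meta $p < 10^{-4}$
(requiring both avoids signals dominated by a few studies), then a greedy
LD prune: rank by marginal p (ties by chromosome, then position), sweep
from the strongest signal removing everything with $r^2 > 0.8$ to it,
continue with the next survivor. All $\binom{k}{2}$ pairs of survivors are
then tested; pairs with discovery $p < 5 \times 10^{-5}$ advance, and the
Bonferroni threshold is $\alpha / \binom{k}{2}$ (for $k = 163$:
$0.05/13{,}203 = 3.79\times10^{-6}$). LD $r^2$ is computed from control
dosages pooled across studies — the paper-level source of LD is not
specified anywhere, and controls avoid case-enrichment distortion of LD;
this is a documented convention of the package. Likewise "mean imputation
$R^2$" is the unweighted mean of per-study values with genotyped SNPs
counted as 1.0. Heterogeneity is reported, never filtered on, by default
(an optional `het_p_min` exists because observed selections tend to have
$P_{het} > 0.1$ anyway).

Because the marginal screen and the ARDI main effects use the same
additive coding, screening on marginal association is independent of the
interaction test, so only the second-stage tests need multiplicity
adjustment. The test suite verifies this independence empirically: across
thousands of null replicates the correlation between marginal and ARDI
interaction Z-statistics is zero within Monte Carlo error.

## Inflation diagnostics and the misspecification guard

For each known locus, the genome-wide interaction p-values are summarised
by the genomic inflation factor
$\lambda = \operatorname{median}(\chi^2_{\text{obs}}) / 0.4549$. If a
locus's true main effect is not log-additive (e.g. a heterozygote-only
effect), the additive-coded main leaves a residual that leaks into every
interaction test at that locus and inflates $\lambda$. The guard rule:
$\lambda \le 1.05$ keeps additive-main ARDI; $\lambda > 1.05$ (strict)
triggers a rerun of that locus with `ardi_umain`, and both $\lambda$
values are reported. The package diagnoses and re-codes; it deliberately
does not apply genomic-control correction to p-values.

## The simulator

`simulate_case_control()` draws population samples — genotypes under
Hardy–Weinberg equilibrium (optionally with LD between the tested pair via
haplotype frequencies with disequilibrium $D$ solved from the target
$r^2$), standardised covariates, and disease from the logistic model
implied by a 3×3 penetrance table of odds ratios, a baseline probability
(default 0.1) and per-study intercept shifts — and rejection-samples until
the case and control quotas are met. Rejection sampling is exact for the
case-control ascertainment at desk-scale sizes, which we prefer over the
retrospective-likelihood shortcut for its simplicity. Imputation noise is
applied afterwards by shrinking the dosage toward its mean and adding
Gaussian noise calibrated so the squared correlation with truth hits the
target $R^2$.

Penetrance presets parameterise the describable two-locus families — null,
multiplicative, carrier-product (`ardi_carrier`), dominant×dominant,
recessive×recessive, threshold, checkerboard, plus fully custom tables —
so that power and calibration comparisons across model families can be
run. These presets are this package's own parameterisation of those
families, not a claim to replicate any particular published simulation
grid. Default study conditions (MAFs 0.3/0.25, modest covariate effects,
baseline prevalence 0.1) are what we consider a realistic mid-size
case-control study; multi-study consortia derive per-study seeds
deterministically from one master seed.

What the simulator does *not* emulate: genome-scale LD structure beyond
pairwise clusters, population stratification beyond supplied PC
covariates, genotyping batch effects, and case-only sampling designs.
Tests passing on these simulations therefore show calibration and recovery
under the stated generative models, not robustness to every artifact of
real consortium data.

## Numerical and design choices

* Missing dosages are `NA`; every pair test is complete-case on the two
  SNPs plus covariates.
* Dosages are hard-called by rounding only where discrete cells are
  required (unrestricted codings, pattern tables).
* Strand-ambiguous A/T and C/G SNPs are flagged, never frequency-flipped:
  near MAF 0.5 frequency-based orientation is unreliable.
* Crude table CIs use the Woolf log-OR method; adjusted CIs come from the
  fit covariance. Tables print ORs to 2 decimals but store full precision;
  the worked-example tests compare at 2 decimals because the published
  in-text arithmetic uses rounded inputs (and only the cells whose printed
  arithmetic is self-consistent at that precision are asserted).
* 1-df tests use Wald statistics because the meta-analysis needs
  per-study $(\hat\beta, \text{SE})$; the unrestricted test uses the LRT.
  Wald and LRT p-values for $\bar\gamma$ agree closely at consortium
  sample sizes (checked in the suite).
* Tie-breaking everywhere is deterministic (p, then chromosome, then
  position), so reruns with the same manifest produce byte-identical
  outputs.

## Problem sizes used in the shipped checks

The calibration checks run at desk scale, chosen to give tight Monte
Carlo error while staying quick on one CPU: type-I error with 1,500 null
replicates of a 2,000/2,000 study (empirical size compared against the
binomial 99% CI around 0.05); screening independence with 3,000 null
replicates of an 800/800 study; the inflation-guard mechanism on three
replicate 1,000/1,000 studies scanned against 800 null partner SNPs each
(pooling 2,400 p-values stabilises the median-based $\lambda$); estimator
recovery with 1,000 seeds of a 5,000/5,000 study at
$\exp(\bar\gamma) = 0.75$, requiring 95% CI coverage of at least 0.93 and
mean bias below 0.02. Published consortium-scale findings (tens of
thousands of samples, 2.1M SNPs) are out of scope for these checks; the
worked-example arithmetic and closed-form meta fixtures are asserted
exactly.

## Known limitations

* The case-only ARDI variant is deliberately not implemented (its control
  independence assumption is fragile under long-range LD), matching the
  published method's scope.
* The carrier score for dosage-only data underestimates carrier
  probability when the minor-homozygote mass is non-trivial; supply `GP`
  probabilities where possible.
* The unrestricted 4-df LRT needs all nine genotype cells populated for
  full df; sparse cells reduce df and, in small studies, the Firth option
  is advisable.
* No BGEN/PLINK-bed input, no imputation, no liftover, no haplotype-level
  tests, no higher-order (3-way and beyond) search.
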