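---
title: "Methods: pooled diversity, differentiation and environmental association along a cline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled diversity, differentiation and environmental association along a cline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcline)
```

`poolcline` analyses pooled resequencing (Pool-seq) data collected along an
environmental gradient. In Pool-seq, DNA from many individuals per population
is sequenced as one library, so only per-site read counts are observed and
allele frequencies must be estimated through two layers of sampling: the
individuals drawn into the pool and the reads drawn from the pooled DNA. Every
method in this package works on that count substrate, stored as a
`site_counts` table parsed from sync files (one A:T:C:G:N:del sextet per pool
per site).

## Pooled diversity estimators

Window estimates of nucleotide diversity, Watterson's theta and Tajima's D
are computed per pool in non-overlapping windows (default 10 kb). Each site is
first subsampled without replacement to a uniform coverage M* (default 30;
multivariate hypergeometric over the six count categories), and alleles seen
fewer than b times (default 2) are treated as absent, which suppresses
sequencing errors at the cost of truncating the site-frequency spectrum to
counts in [b, M*-b]. The estimators correct for this truncation under the
neutral spectrum:

* pi: per-site heterozygosity `h = (M/(M-1))(1 - sum f^2)` over passing
  alleles, summed over the window and divided by
  `f_pi(M, b) = 2/(M(M-1)) * sum_{i=b}^{M-b} (M - i)` times the usable length;
  `f_pi(M, 1) = 1` recovers the classical estimator.
* theta_W: segregating sites (at least two alleles with count >= b after
  subsampling) divided by the truncated harmonic sum
  `a_W(M, b) = sum_{i=b}^{M-b} 1/i` times the usable length.
* Tajima's D: the corrected window totals are contrasted and scaled by the
  classical Tajima variance constants at sample size M*, with `a_1` replaced
  by `a_W(M, b)`. This variance is an approximation — the property used for
  validation is that the mean D over neutral windows is near zero, with the
  sign always equal to `sign(pi - theta_W)`. `D` is undefined (`NA`, never 0)
  below two segregating sites.

Two deliberate simplifications are documented here. First, with pool size
n = 100 far above M* = 30, reads are treated as draws from the pool's allele
frequency; the residual bias is O(M/n), under 2% in the default design.
Second, sync tables produced by the generator list variant sites only, so
unlisted sites are counted as covered invariant sites; under the Poisson(90)
coverage model the probability of a site falling below M* = 30 is negligible,
making the usable length effectively the window length. Windows with fewer
than half their sites usable are reported but flagged `NA`.

## Differentiation scan

Per-SNP F_ST uses the heterozygosity decomposition
`(pi_total - pi_within) / pi_total` with unbiased per-site heterozygosities;
negative finite-sample values are clamped to zero (counted), fixed differences
give exactly 1. A site is a SNP when at least two alleles reach a summed
across-pool count of 4. Outliers are taken from the empirical upper tail
(type-7 quantiles, default 0.5% per SNP and 5% per gene, ties included), with
the SNP-level tail pooled across all pairs — consistent with treating the
15 pairwise comparisons as one F_ST distribution. Gene scores default to the
maximum of the per-pair mean F_ST within the gene; mean or a named pair are
available since no single convention is canonical. Allele-frequency contrasts
are tested per pair with Fisher's exact test and a Bonferroni family
correction (0.05/15 ≈ 0.003).

SNPs are classified genic/intergenic with genic SNPs subclassified coding,
exonic or intronic (a SNP in any exon of overlapping genes is exonic;
exon-and-CDS is coding; genic beats promoter), and intergenic SNPs within
600 bp upstream of a strand-aware gene start are promoter SNPs. The
classification partitions: genic plus intergenic equals the SNP total.

For differentially fixed SNPs between clusters, the noise filter is applied
*within each cluster*: an allele with a cluster-summed count below 4 is
treated as sequencing noise there. A global filter would never remove a stray
read of the allele fixed in the opposite cluster, so a single error would
break fixation — contrary to the intent of the min-count rule.

Short haplotype loci for coalescent-based downstream analyses are extracted
as the leftmost maximal SNP run per scaffold spanning under 90 bp with at
least 3 SNPs and at least 20 bp, keeping loci whose spanning-read coverage is
within [15, 100] in every population, and sampling 20 read-backed haplotypes
per population per locus (seeded).

## Structure and admixture

The per-SNP pairwise F_ST distributions are reduced to five quantile distance
matrices (levels 0.975, 0.75, 0.5, 0.25, 0.025) and ordinated jointly with
DISTATIS: each matrix is double-centered (dissimilarities are centered
directly, the standard convention for non-Euclidean inputs), normalized by
its first eigenvalue, weighted by the first eigenvector of the RV-coefficient
matrix, and the weighted compromise is eigendecomposed into factor scores.
Bootstrap over SNPs yields 95% normal-approximation ellipses on the first two
axes. At desk scale a low quantile level can be all zero (the clamped mass at
F_ST = 0); such uninformative matrices are dropped by the pipeline before
ordination with a message.

f3(target; A, B) and f4(A, B; C, D) are allele-frequency product statistics;
a significantly negative f3 marks the target as admixed. Standard errors use
a delete-one block jackknife over consecutive 500-SNP blocks (robust to
linkage), and |z| > 3 is the significance rule. Because pool frequencies are
estimated from reads, f3 subtracts a finite-sampling term
`p(1-p)/(M-1)` (read layer) plus `p(1-p)(1-1/M)/n` when the pool size is
known; both can be disabled. Neighbor-joining trees (via ape) summarize the
median-F_ST and covariance-correlation matrices, with negative branches
clamped to zero and their excess moved to the sister edge. The Mantel test is
a direct permutation of rows/columns with `p = (count + 1)/(n_perm + 1)`;
identity permutations are redrawn so the observed configuration enters only
through the `+1`.

## Environmental association

The 19 bioclimatic covariates plus elevation are standardized and summarized
by PCA into one composite axis (`env1`). The neutral among-population
covariance Omega is estimated by the method of moments from a seeded
subsample of 10,000 polymorphic SNPs using standardized deviations
`x = (p - pbar)/sqrt(pbar(1-pbar))`, with the expected read-noise
contribution removed from the diagonal and the result projected to the
nearest positive semi-definite matrix; a second subsample gives a convergence
metric (max absolute difference of the correlation forms). Per SNP, the model
`p = alpha + beta * env1 + eps`, `eps ~ N(0, sigma2 * Omega + read noise)`
with `sigma2 = pbar(1-pbar)`, is integrated over the intercept analytically
and over beta on a 401-point grid under a zero-mean normal prior whose
+-3 SD span the frequency range across the environmental spread. The support
statistic `Z = |P(beta > 0 | data) - 0.5|` is bounded by 0.5 (its maximum
marks saturated support), and the Bayes factor compares the free-beta model
to `beta = 0`. This is a deterministic grid-posterior analogue of the MCMC
machinery used for such scans; identity with any particular sampler's output
is not claimed, and with identical frequencies across pools the Bayes factor
correctly falls below 1 (evidence for the null) while Z is 0. Candidate
overlap between the environmental and F_ST rankings is reported as
`100 * |intersection| / |env set|`.

## GO enrichment

Annotations are propagated up the is_a DAG (true-path rule), the universe is
every annotated gene, and terms with more than three annotated genes are
tested from most specific to most general (longest-path depth, ties
lexicographic). When a term's p-value falls below 5%, its current genes are
removed from all ancestors before those are tested (the elim decorrelation).
The reported p-value is the smaller one-sided hypergeometric tail with the
direction of departure attached: after elimination an ancestor that has lost
its signal genes is typically *under*-represented, and the smaller-tail
convention makes that loss of significance explicit and keeps the worked
arithmetic of the two-level example exact (child 6.45e-5; parent 0.0163
before, 0.194 after elimination). A pure over-representation test is
available via `alternative = "greater"`. No multiple-testing correction is
applied across terms by default.

## Trait statistics

Small-sample comparisons use the exact Mann-Whitney test (two-sided p as the
doubled smaller tail, capped at 1; exact only without ties and for
`n_x * n_y <= 10000`, otherwise a tie-corrected normal approximation with a
warning) and Welch's t-test. Gas-exchange response curves of net
photosynthesis against thallus water content are least-squares polynomials
(degree 3 by default — the curves are unimodal and the degree is otherwise
unconstrained by the data available), reporting r^2, the fitted maximum over
the observed range and the water-content interval keeping the curve at or
above 90% of that maximum, the optimal-water-saturation criterion used to
contrast highland and lowland ecotypes.

## The synthetic-data generator

`simulate_gradient_experiment()` emulates the sampled design: six pools of
100 haploid individuals at 90x mean Poisson coverage with base error 0.002,
on 200 scaffolds of mean length 10 kb (about 0.02 SNPs/bp). Frequencies
follow a hierarchical Balding-Nichols model: ancestral `p0 ~ U(0.05, 0.95)`;
two cluster frequencies with drift `F_div = 0.1`; pools 1-4 around cluster A
and pool 6 around cluster C with within-pool drift `F_pop`; pool 5 mixes the
clusters 50:50 before its own drift. `F_pop` defaults to 0.01: an admixed
pool's f3 expectation is roughly
`-lambda(1-lambda) * 2 * F_div * p0(1-p0) + F_pop * p0(1-p0)`, so detectable
admixture — the scenario being emulated, where every triplet with the middle
pool as target is significantly negative — requires post-admixture drift well
below `2 * lambda(1-lambda) * F_div = 0.05`. One percent of loci are
"selected": their pool frequencies receive an additive logit shift
`beta * altitude_std` with `beta = 2` by default, a strong cline spanning
about five logits end to end, calibrated so that a covariance-controlled scan
at this design's depth recovers most of them. The environmental table couples
altitude with 19 covariates that are linear in altitude plus standardized
noise of SD 0.15, keeping the first principal component above 95% of the
variance (around 98% in practice). Reads are drawn in two stages (binomial
pool sampling, then binomial read sampling with uniform base-substitution
errors), so the frequency variance decomposes as
`p(1-p)(1/n + (1-1/n)/coverage)`.

`simulate_neutral_windows()` draws an independent standard-coalescent
genealogy per window (no recombination within, independence between),
places infinite-sites mutations at rate theta per site and pushes the sample
frequencies through the same read model — the validation harness for the
diversity estimators, with `E[S] = theta * a_{n-1} * L` available in closed
form.

What the generator does *not* emulate: linkage within windows of the gradient
dataset (SNPs are drawn independently), selection at linked sites, coverage
heterogeneity beyond Poisson, mapping artefacts, and diploidy (the organism
modeled is haploid). Passing tests therefore demonstrate correctness of the
estimators and the detection machinery under the stated sampling model, not
robustness to alignment or demographic misspecification.

## Numerical choices and problem sizes

Quantiles are type-7 throughout with ties flagged inclusively. Grids: 401
posterior points over +-4 prior SD; response-curve optima on a 2001-point
grid over the observed range. Ridge of 1e-6 guards near-singular covariance
solves; PSD projection clamps negative eigenvalues at zero. The
validation suites run at 500 neutral windows, about 20,000 SNPs for the
cline scenarios, 20 seeded replicates for the admixture detection rate, and
10,000-SNP covariance subsamples — sizes chosen so each property is measured
with comfortable Monte-Carlo margin on a single CPU. All randomness flows
from explicit integer seeds; per-stage streams in the pipeline are derived
from the master seed by fixed offsets so stages are independently
reproducible.

```{r example, eval = FALSE}
dat <- simulate_gradient_experiment(sim_config(n_scaffolds = 50), seed = 1)
ft  <- pairwise_fst_table(dat$counts)
pf  <- pool_frequencies(dat$counts)
f_statistic(pf$freq, c(5, 1, 6), "f3", pf$depth, pool_size = 100)
```
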