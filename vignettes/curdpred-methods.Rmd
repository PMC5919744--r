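---
title: "curdpred: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{curdpred: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`curdpred` reimplements, as one tested toolkit, the analysis workflow
used to characterize small, strongly structured diversity panels —
gene-bank accessions genotyped by sequencing and phenotyped in
replicated multi-environment trials: variance-component phenotype
modelling, population structure, linkage disequilibrium, mixed-model
association, and cross-validated genomic prediction. This vignette
explains the models and the reasoning behind parameter defaults and
numerical choices. It states no empirical result beyond what the test
suite and the acceptance script compute themselves.

## The phenotype model and heritability

Plot records are modelled as
$y_{ijk} = \mu + G_i + E_j + GE_{ij} + e_{ijk}$ with genotype,
environment and interaction effects random and only the intercept
fixed. `fit_two_way_random()` delegates the REML fit to
`lme4::lmer()`. We deliberately use an established REML fitter rather
than writing our own EM iteration here: the two-way random model is a
completely standard fit, lme4 handles unbalanced data and boundary
variance components robustly, and correctness is pinned by a test that
compares its output with the closed-form Henderson method-3 ANOVA
estimators on balanced data (agreement to 1e-6). The mixed-model
machinery that *is* part of this package's contribution — the
kinship-based REML used by the association scan and GBLUP — is authored
in the package (see below).

Broad-sense heritability is reported on an entry-mean basis,
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(re))$,
with $e$ the number of environment levels and $r$ the median replicate
count — the natural generalization when the design is mildly
unbalanced. Variance components at the zero boundary are clamped to 0.
Genotypic correlations are Pearson correlations of per-genotype BLUPs;
phenotypic correlations use per-genotype entry means, since the
adjustment step behind published "adjusted means" is rarely specified.

## The synthetic world

The generator's defaults describe the panel the package is designed
for, and they are fixed rather than tuned: 174 individuals, 9
chromosomes of 1200 markers (about $10^4$ SNPs), 5 clusters,
per-individual missingness drawn uniformly from 19.02–76.73%, 6
environments with 2 replications, and an oligogenic default trait (10
QTL, entry-mean $H^2 = 0.8$ within the observed 0.1–0.94 range).

*Differentiation.* Cluster allele frequencies follow the
Balding–Nichols model: with ancestral frequency $p$, each cluster draws
from $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, so Wright's $F_{ST}$
has expectation $F$. No per-cluster $F_{ST}$ is published for the
motivating panel; the default $F = 0.2$ was chosen once as a value at
which five clusters are cleanly separable by k-means on PCs (the
regime the study describes), and is not revisited.

*Linkage disequilibrium.* Haplotypes follow a first-order Markov copy
process on a latent uniform variable: at each next marker the latent
value is copied with probability
$c_j = \rho^{\,\mathrm{gap}_j/\overline{\mathrm{gap}}}$
(`ld_correlation` $\rho$, attenuating with bp distance), otherwise
redrawn. Copying the latent quantile rather than the allele preserves
marginal frequencies exactly while inducing positive, distance-decaying
correlation. This is a desk-scale substitute for coalescent simulation:
it reproduces the two features downstream code relies on (adjacent-pair
LD and its decay) but not recombination hotspots, allele-frequency/LD
coupling, or realistic haplotype block structure.

*Missingness* is completely at random within an individual, at an
individual-specific rate drawn from the configured range — matching
the published per-genotype summaries. Real genotyping-by-sequencing
missingness is coverage-correlated along the genome; that refinement
is out of scope, so imputation accuracies measured on simulated data
are optimistic.

*Truth bookkeeping.* QTL effects are drawn once and rescaled so the
panel's genetic variance equals its target exactly; interaction and
residual noise are split equally to meet the target $H^2$ given
$(e, r)$. Recovery tests therefore have a stable truth rather than a
resampled one.

A green test on this world establishes that the estimators recover the
stated generative structure; it does not establish performance on real
panels with coverage-driven missingness, cryptic relatedness, or
selection-shaped LD.

## Genotype handling

MAF is computed over non-missing calls only — with up to 77% missing
calls per individual anything else is unusable. Filtering applies the
MAF < 0.05 rule and, optionally, a zero-missingness rule, yielding the
strict "unimputed" data set; a marker failing both is counted under the
MAF rule so the report partitions cleanly. The imputer is a declared
surrogate: a windowed k-nearest-neighbour concordance vote (defaults
w = 20 flanking markers, k = 5 donors, frequency-weighted tie-break),
*not* a reimplementation of haplotype-cluster HMMs. The contract
downstream stages rely on is only that the matrix becomes complete and
observed calls are untouched; the tests verify that, with LD present,
the windowed imputer strictly beats a frequency draw on masked truth.
VCF reading goes through `VariantAnnotation::readVcf` (biallelic SNPs
retained, multi-allelics dropped with a count); writing emits a minimal
GT-only VCF 4.2 directly, which round-trips through the reader.

## Structure

PCA is computed on centered, frequency-scaled dosages
($\sqrt{2p(1-p)}$), mean-filling missing calls for the decomposition
only; the retained-PC default captures 90% of variance. Cluster number
is chosen by k-means (20 restarts) over candidate K scored with
$BIC(K) = n\log(WSS/n) + K\log n$, the within-sum-of-squares Gaussian
convention of DAPC-style find-clusters. Discriminant axes are fitted by
LDA on the retained PC scores and back-projected to markers; squared
loadings per axis are normalized to sum to one.

The structure-corrected kinship regresses each marker on leading PCs
and rebuilds the VanRaden matrix from residuals. This is a
PC-residual surrogate inspired by PC-Relate, not the full estimator
(no individual-specific allele-frequency model). With `n_pcs = "auto"`
only PCs whose eigenvalue exceeds the Marchenko–Pastur upper edge
(with a 5% margin) are removed. The threshold matters: removing a
fixed number of PCs from an unstructured panel necessarily strips
$\approx \sqrt{2/n}$ of the kinship's Frobenius norm even when there
is no structure at all, whereas the eigenvalue test leaves a panmictic
panel untouched and still zeroes between-cluster relatedness in
structured ones.

## Linkage disequilibrium

Haplotype frequencies for unphased dosage pairs come from the standard
two-locus EM (only the double heterozygote is phase-ambiguous),
converged to 1e-10; $r$ is signed with orientation fixed by the shared
reference allele, and $r^2 = r^2$ exactly by construction. One
numerical honesty note: the EM estimate can only match *realized*
haplotype counts up to the information lost in double heterozygotes —
at moderate LD that gap is irreducible and of order $1/\sqrt{n}$, so
the phased-truth test uses a strong-LD, large-$n$ construction where
the gap is below 1e-3.

Background LD is the 95th percentile of $r^2$ over randomly sampled
inter-chromosomal pairs (the published phrase "correlation of the 95%
percentiles" is grammatically ambiguous; this is the reading that
matches an exhaustive-pair oracle). Decay is fitted by nonlinear least
squares to the Hill–Weir drift expectation of $r^2$ with the
sample-size term — the standard choice where a source says only
"nonlinear regression curve" — and the decay-meets-background distance
is solved numerically over the whole chromosome span (the fitted curve
is parametric; restricting the root search to observed pair distances
would spuriously flag "no intersection" in long-LD panels). If the
curve never crosses the background, the intersection is flagged
undefined rather than extrapolated.

Persistence of linkage phase computes signed $r$ for the same marker
pairs in two samples sharing one map, orders pairs by distance,
correlates the paired $r$ values within 50-pair bins, and averages the
bins — the binning convention that keeps samples with different marker
information comparable.

## Association mapping

The kinship is VanRaden's first method (centered cross-product over
$2\sum p(1-p)$, diagonal ridge 1e-6); the construction used by the
original study is unstated, and VanRaden is the field default. The
association engine estimates the null variance components once by REML
through the eigendecomposition of K — profiling the likelihood over
$\delta = \sigma^2_e/\sigma^2_a$ on a 73-point log grid refined by
golden-section search in the best bracket (bounds $e^{\pm 18}$) — and
then tests every marker by GLS on the rotated data with components
fixed: the EMMAX approximation. The default test is Wald $\chi^2_1$;
an F variant with the per-marker residual variance is provided, and
reduces exactly to single-marker OLS when K is the identity (a test
asserts this to 1e-10). P-values are floored at the smallest positive
double so they stay in (0, 1].

The multi-locus scan adds the currently most significant marker as a
fixed cofactor, re-estimates variance components, and repeats; model
choice uses an extended BIC with penalty $\log n + 2\log m$ per
cofactor, computed from the ML likelihood evaluated at the REML
estimates — REML likelihoods are not comparable across fixed-effect
sets, and using them (we tried) selects spurious cofactors under a
polygenic null. A multiple-Bonferroni criterion is available as the
alternative. The backward pass re-tests each cofactor given the others
(variance components re-estimated) and drops the weakest while its
conditional p exceeds $\alpha/m$.

λ is the ratio of the observed to expected median $\chi^2_1$ statistic.
FDR uses the Benjamini–Hochberg step-up at Q = 0.2 per trait and data
set; where the source material ambiguously mentions both 0.05 and 0.2,
the methods statement (0.2 for all data sets) is followed. Per-QTL
summaries report $R^2_{adj} = R^2 - z(1-R^2)/(N-z-1)$ and
$\hat\rho = R^2_{adj}/\hat H^2$, with $\hat\rho > 1$ flagged rather
than truncated (it can legitimately overshoot when $R^2_{adj}$
captures structure-correlated signal).

## Genomic prediction

GBLUP solves $y = 1\mu + g + e$, $g \sim N(0, \sigma^2_g K)$, with
REML components re-estimated inside every training fold (no leakage)
and held-out genetic values predicted through the kinship cross-block.
RRBLUP is built to make the classical equivalence exact: the ridge
level comes from REML on $K = WW'/2\sum p(1-p)$ *without* a ridge
term, so $X\hat\beta$ equals the GBLUP genetic values to machine
precision — the empirical "RRBLUP equals GBLUP" observation becomes an
exact test (1e-8) rather than an approximate one.

BayesB is a Gibbs sampler (Rcpp) over marker effects with a point mass
at zero and a scaled-t slab: per-marker variances carry a scaled
inverse-$\chi^2$ prior (df 5), the inclusion probability $\pi$ a Beta
prior (mean 0.5, prior count 10), and the slab scale is solved from a
prior marker-explained variance of 0.5 of the phenotypic variance —
the usual genomic-prediction heuristic. The default chain is 5000
iterations, 1000 burn-in, thinning 5; draws use R's RNG so chains are
seed-deterministic. These defaults are declared and configurable; the
reference implementation this mirrors is not available in this
environment, so correctness rests on planted-QTL recovery, degenerate
limits, and cross-chain reproducibility tests.

Cross-validation uses fresh random 5-way partitions per replication;
prediction ability is the Pearson correlation between observed
phenotypes and predicted genetic values per held-out fold, averaged
(a pooled-per-replication variant is a flag, since sources are often
ambiguous between the two). Effect rankings order markers by |effect|
with p-value and then marker-order tie-breaks, deterministically.

## Pipeline

`run_pipeline()` drives simulate/read → filter → impute → phenotype
model → structure → LD → association → prediction from one YAML or
JSON config, validating paths before any compute, writing per-stage
tab-delimited tables and JSON summaries plus a manifest with md5
checksums. A single global seed expands to fixed per-stage sub-seeds
(`seed + 1000·stage`), so deterministic stages reproduce checksums
across reruns and any stage can be rerun in isolation. The exported
functions and config files are the primary interface; a thin
`inst/cli/curdpred` wrapper exposes `simulate` and `run` for shell use.

## Known limitations

- The imputer is a neighbourhood vote, not a haplotype HMM; its
  accuracy advantage is demonstrated relative to a frequency baseline,
  not to fastPHASE/BEAGLE.
- The structure correction is a PC-residual approximation to
  PC-Relate; close-relative structure that PCs miss is not removed.
- The simulator's LD is Markovian and its missingness MCAR, so
  real-data imputation and prediction figures should be expected to be
  less favourable than simulated ones.
- Test scales for a few brute-force invariants are reduced from their
  exhaustive statements (noted inline in the tests) to keep the suite
  within minutes; the acceptance-scale experiments are run as stated.
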