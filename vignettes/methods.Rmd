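---
title: "Methods: polygenic scores, ERP clustering, and causal mediation in erpmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores, ERP clustering, and causal mediation in erpmed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmed)
```

## The scientific question

Event-related potentials (ERPs) are stereotyped electrophysiological
responses whose impairment is heritable and common in psychotic illness.
When subjects are clustered over six ERP summary measures — P50 sensory
gating ratio, S1 amplitude, N1 amplitude, P2 amplitude, P3 amplitude and P3
latency — a "globally impaired" subgroup emerges that is abnormal on all
six. `erpmed` implements the full inference chain for asking whether this
neurophysiological phenotype lies on the causal path between common genetic
variation and positive psychotic symptoms:

1. genotype quality control and ancestry principal components;
2. polygenic risk scores (PRS) from discovery GWAS summary statistics by LD
   clumping and P-value thresholding;
3. K-means clustering of the six ERP measures, with the number of clusters
   chosen by V-fold cross-validation, dichotomized into globally impaired
   vs not;
4. logistic PRS–phenotype association with Nagelkerke incremental pseudo-R²
   and false-discovery-rate adjustment across the trait-by-threshold grid;
5. regression-based counterfactual mediation — natural direct and indirect
   effects of a PRS quartile contrast on the PANSS positive total through
   cluster membership — with bias-corrected bootstrap intervals and a
   sensitivity analysis to unmeasured confounding.

Because individual-level data of this design are not publicly available,
the package ships a synthetic-cohort generator whose defaults emulate the
design: 383 subjects (136 schizophrenia, 122 psychotic bipolar, 125
controls before QC), a latent three-cluster ERP structure with roughly 60
globally impaired members, a PRS effect on impaired-cluster membership, and
a configurable exposure–mediator–outcome chain. Every stage of the pipeline
is exercised and validated against this generator.

## The synthetic cohort generator

**Genotypes.** Per-variant minor allele frequencies are uniform on a
configurable interval (default 0.05–0.5). Haplotypes come from a Gaussian
copula: within blocks of `ld_block_size` consecutive variants (default 50)
latent normals follow an AR(1) process with lag-one correlation
`within_block_r` (default 0.8); thresholding each latent at the
allele-frequency quantile yields an allele, and a genotype is the sum of
two independent haplotypes. Blocks are independent, giving controllable,
block-structured LD without any real reference panel. Missingness is
applied completely at random (default 0.5%).

The default panel holds 20,000 variants. This is far below a real array
(~660k autosomal SNPs) but deliberately large enough for the
method-of-moments relatedness estimator: PI-HAT at the conventional 0.125
exclusion threshold is dominated by Poisson noise in the rare IBS-0 events,
and below roughly ten thousand pruned markers the estimator's sampling
tail produces false-positive "related" pairs. At the default panel size
the post-pruning panel (~11k markers) keeps that false-positive mass
negligible while a full simulation-plus-QC round stays under a minute.

**Discovery summary statistics.** Each simulated trait draws `n_causal`
(default 50) causal variants with effects from N(0, 0.1²); reported
effects add estimation noise with standard error `1/sqrt(2 N p (1-p))` at
discovery size `N` (default 50,000), and P values are two-sided normal
tails. Four traits are simulated by default, mirroring a
schizophrenia / bipolar / educational-attainment / childhood-intelligence
discovery panel; only the first drives the phenotypes, so the remaining
three act as realistic nulls.

**Phenotypes.** The true polygenic score `Z` (dosages weighted by true
effects, standardized) enters a logistic model for membership in the
globally impaired cluster, `logit P(M=1) = -1.75 + 0.5 Z` by default,
giving a marginal impaired fraction of ~15.7% (≈60 of 383). The six ERP
measures are drawn from the member cluster's normal distributions. The
default cluster means are spaced two within-cluster standard deviations
apart per measure between adjacent clusters — a strongly separated
configuration chosen so that the latent structure is recoverable at the
design's sample size, which is what the clustering-recovery checks
require; real ERP clusters overlap more, so passing those checks speaks to
the correctness of the clustering code, not to the detectability of real
ERP subgroups. Per-cluster means and dispersions of the emulated study are
not published; the defaults are free parameters in the documented ranges
of the six measures, with the impaired cluster worst on every measure
under the direction convention below.

Diagnosis is multinomial conditional on cluster with the design's margins
(impaired: 48.3/43.3/8.3% SCZ/BPD/control; non-impaired: 33.1/29.7/37.2%);
age and smoking are cluster-conditional (impaired older and more often
smokers), sex is Bernoulli, and chlorpromazine-equivalent dose is
lognormal for cases only. The PANSS positive total follows

```
panss = t0 + t1 * A + t2 * M + t3 * A * M + sigma * e
```

with defaults `t0 = 16, t1 = 0.5, t2 = 3.75, t3 = 0, sigma = 7`, observed
for 161/258 of cases, missing completely at random. The generating
exposure `A` is the *score-quartile class* of `Z` (1 top quartile, 0
bottom quartile, 0.5 middle): the direct effect is applied on the same
top-vs-bottom-quartile contrast that the downstream mediation analysis
estimates. Had `t1` instead multiplied the continuous score, the
within-quartile score variation would act as an unmeasured
mediator–outcome confounder after dichotomization, making the generating
"proportion mediated" unrecoverable by any regression-based estimator —
an estimand mismatch, not an estimator defect. With the contrast-scale
definition the generating truth and the method's estimand coincide, so
parameter-recovery simulations are a clean test of the machinery.

One master seed drives per-stage substreams (genotypes / per-trait effects
/ phenotypes / bootstrap / sensitivity), so identical configurations give
bit-identical cohorts and stages can be regenerated independently.

**What the generator does not emulate.** Raw EEG waveforms (measures are
generated at the summary level), realistic human LD maps, imputation
uncertainty, genotyping batch effects, population stratification (unless
configured through allele-frequency divergence), and informative
missingness. Passing tests on this generator therefore validates the
statistical machinery, not robustness to those real-data complications.

## Genotype quality control

Variant filters run in a fixed order — sex chromosomes, call rate < 98%,
minor allele frequency < 0.05, Hardy–Weinberg exact-test P < 1e-6 — each
variant reported once with the first reason that applied. The HWE test is
the exact conditional test (all heterozygote counts compatible with the
observed allele counts enumerated; configurations no more probable than
the observed one summed), which is the appropriate choice in the stringent
1e-6 regime where chi-square approximations are unreliable. It is applied
to all samples; restricting to controls is a configuration decision left
to the caller since the emulated design does not state one.

Sample filters remove missingness > 5% and heterozygosity outliers beyond
3 SD. The heterozygosity cut is iterated to a fixed point (mean and SD
recomputed on retained samples until no new outlier appears), which makes
the filter idempotent — a one-pass relative cut is not, because removing
an extreme outlier shrinks the SD.

Relatedness uses method-of-moments IBD on an LD-pruned panel (r² < 0.2 in
100-variant windows): expected IBS-class probabilities given IBD state are
accumulated from allele frequencies, solved for Z0, Z1, Z2, and
`PI-HAT = Z2 + Z1/2` clamped to [0, 1]. The allele-frequency functionals
(p²q², p³q, …) use unbiased factorial-moment estimators from the sample
allele counts; plug-in frequencies visibly inflate PI-HAT on panels of a
few thousand markers. Within a flagged pair (PI-HAT > 0.125) the sample
with higher missingness is removed, ties broken lexicographically.

Ancestry PCs standardize dosages EIGENSTRAT-style (mean-impute, center at
2p, scale by sqrt(2p(1-p))) and take top left singular directions; the
default of 3 components matches the association model below.

## ERP clustering

Measures are z-scored before K-means because their units are
incommensurate (percent, microvolts, milliseconds); without
standardization P3 latency would dominate every distance. Lloyd's
algorithm runs from k-means++ starts with 50 restarts (seed exposed),
keeping the best inertia; clusters are canonically relabelled by ascending
centroid norm so results are invariant to sample order.

**Choosing K.** For each candidate K (2–5), a V-fold split (default
V = 10) fits on the training folds and scores held-out points by squared
distance to the nearest trained centroid. The raw held-out error is
non-increasing in K in expectation even for structureless data — more
centroids are always nearer, at the quantization rate K^(−2/d) in d
dimensions (measured: ~7% per step for a single 6-D Gaussian). A literal
argmin therefore always drifts to the top of the candidate range and can
never return the true K. Selection consequently minimizes the
dimension-adjusted score `error(K) · K^(2/d)`, which cancels the
structureless gain: it is flat for a single Gaussian (ties resolve to the
smallest K) and dips sharply at the true number of well-separated
clusters. Raw errors are reported alongside the scores.

**Labelling the impaired cluster.** Each standardized centroid coordinate
is multiplied by its impairment direction — +1 where higher is worse (P50
ratio, P3 latency), −1 where lower is worse (S1, N1, P2, P3 amplitudes;
N1 is operationalized on its magnitude, so a smaller value means a weaker
negative-going component). The cluster whose aligned centroid is largest
on *every* measure is the globally impaired one. If no cluster dominates
on all six, the largest rank-sum is used and the model flagged for review;
a rank-sum tie is an error demanding a manual look at the direction
vector. The direction convention is configurable because the sign in
which "abnormality" should be read on N1 is a substantive choice, not a
statistical one.

## Polygenic scoring

Summary statistics are harmonized to the target panel by chromosome and
position: effects on the target's alt-dosage scale, sign-flipped when the
effect allele matches the target reference, strand-ambiguous A/T and C/G
variants dropped. Clumping is greedy: variants visited in ascending P
(ties by chromosome, then position, for determinism), each index variant
removing not-yet-retained neighbours within ±250 kb whose dosage r² with
it exceeds 0.1, with the target sample acting as its own LD reference
(mean-imputed, centered dosages). The extended MHC region (chromosome 6,
26–33 Mb, 1-based inclusive) is removed before clumping. Scores at each
P-value threshold (defaults 0.001, 0.01, 0.05, 0.1, 0.5) are weighted
allele sums over index variants with `p ≤ threshold`; missing dosages are
replaced by twice the effect-allele frequency in the target sample, the
convention that keeps a missing genotype score-neutral in expectation.

## Association testing

Each trait-by-threshold score enters `GI ~ score + PC1 + PC2 + PC3` by
maximum-likelihood logistic regression; the Wald P for the score
coefficient is reported with the Nagelkerke pseudo-R² *increment* of the
score over the covariate-only model, floored at zero (the full-model R² is
available via `incremental = FALSE`, since published reports do not always
state which convention they print). Quasi-separation is detected by a
perfect fit of the response or diverging coefficients without IRLS
convergence — boundary fitted probabilities alone are not evidence, since
legitimate fits can produce extreme linear predictors. FDR adjustment is
Benjamini–Hochberg step-up across the 20 tests per subset (4 traits × 5
thresholds); BH is deterministic, needs no tuning, and at m = 20 differs
from Storey-type q-values only through the pi0 estimate.

The demographic comparison block uses pooled-variance two-sample t tests
from group summaries, Pearson chi-square without continuity correction
(verified to reproduce published contingency statistics at printed
precision), and OLS with classical covariance for covariate-adjusted
contrasts — all available-case.

## Counterfactual mediation

The exposure is the top-vs-bottom quartile contrast of a chosen score
(middle half excluded; ties at a boundary stay in the extreme group), the
mediator is binary cluster membership, and the outcome is continuous
(PANSS positive; linear model) or binary (logistic with the rare-outcome
approximation). With mediator model
`logit P(M=1|A,C) = b0 + b1 A + b2'C` and outcome model
`E[Y|A,M,C] = t0 + t1 A + t2 M + t3 AM + t4'C`, the natural effects for
the contrast `a = 1` vs `a* = 0` at covariate value c are, in the linear
family,

```
NDE = (t1 + t3 expit(b0 + b1 a* + b2'c)) (a - a*)
NIE = (t2 + t3 a) (expit(b0 + b1 a + b2'c) - expit(b0 + b1 a* + b2'c))
```

with total = NDE + NIE exactly and proportion mediated PM = NIE/total; in
the logistic family the corresponding odds-ratio expressions are reported
as log odds ratios, with PM on the odds-ratio scale. Effects are evaluated
at the covariate means of the analysis subset — the formulas are
covariate-conditional and some evaluation point must be fixed; the mean is
the conventional choice. The primary correctness oracle in the test suite
is a Monte-Carlo counterfactual simulation that draws M under one exposure
level and evaluates the outcome model under another, directly from the
definition E[Y(a, M(a*))]; the formulas agree with it to Monte-carlo error
(the logistic family carries an additional ~1% rare-outcome approximation
at outcome prevalences near 0.5%).

**Intervals.** Individuals are resampled with replacement within the
analysis subset (200 replications by default) and both models refitted.
NDE, NIE and the total effect get 95% bias-corrected percentile intervals
(z0 from the fraction of bootstrap estimates below the point estimate; no
acceleration term — the method matches its name, "bias-corrected", without
assuming more). The proportion mediated is a *ratio*, and its bootstrap
distribution wraps through infinity whenever the total-effect draws cross
zero, where percentile-type intervals are defective. Its interval is
therefore a Fieller-type inversion: the set of candidate proportions p for
which the BC interval of `NIE − p·total` covers zero. This reduces to the
expected behaviour when the total effect is well identified and correctly
returns very wide or unbounded intervals when it is not.

**Sensitivity to unmeasured confounding.** For each requested strength
pair (r with the mediator, r with the outcome) a standard-normal
confounder U is constructed by the conditional-Gaussian route
`U = c1·ZM + c2·ZY + s·e`, with (c1, c2) solving the 2×2 system that fixes
the target correlations given the observed mediator–outcome correlation
(jointly infeasible targets raise an error); both models are refitted with
U and effects averaged over 100 seeded draws. The zero-strength setting
returns the unadjusted estimates exactly rather than averaging over pure
noise covariates. Correlating U with the observed binary mediator
(point-biserial) is one of two readings of "correlation with the
mediator"; the latent-liability reading would correlate U with the
mediator model's linear predictor instead and gives the same qualitative
attenuation behaviour.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS to 1e-10, 100 iterations; rank deficiency and
  (quasi-)separation are errors naming the offending column.
* `nagelkerke_r2` clamps to [0, 1] and returns 0 when the null model is
  already saturated.
* K-means: duplicate points fewer than k distinct is an error; a
  zero-variance measure is left unscaled rather than divided by zero.
* A constant score column yields a zero R² increment by definition rather
  than a rank-deficiency error.
* Degenerate score distributions (equal quartiles) and constant mediators
  are errors, not silent zeros.
* Bootstrap replicates that fail to fit are dropped; more than 20%
  failures is an error reporting the rate.
* Monomorphic variants return HWE P = 1 (no test possible) and are
  excluded from PCA with a warning.

## Problem sizes used in the checks

The test suite and the acceptance script run the generator at the design's
sample size (n = 383) with variant panels of 400–20,000 depending on what
the check needs: scoring and mediation checks use small panels (the score
only needs enough causal variants), QC and pipeline checks use panels
large enough for stable PI-HAT, and clustering checks draw ERP profiles at
n = 400 directly from the cluster model. Bootstrap intervals use the
default 200 replications; coverage checks use 30–50 replicate cohorts.

## Known limitations

* The rare-outcome logistic mediation formulas are approximations;
  prevalences above a few percent inflate the reported log odds ratios.
* PI-HAT needs thousands of quasi-independent markers; panels below ~5k
  pruned variants produce unstable estimates (flagged by a warning below
  50).
* The sensitivity analysis is one concrete construction of a hypothetical
  confounder; it quantifies robustness under that construction, not under
  all possible confounding.
* The V-fold selection score assumes the candidate clusters are roughly
  isotropic in standardized space; strongly anisotropic cluster shapes
  would need a different penalty exponent.
* No imputation, phasing, batch correction, X-chromosome checks, or
  cross-ancestry weighting.
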