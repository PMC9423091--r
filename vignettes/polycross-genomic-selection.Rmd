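---
title: "Genomic selection in polycross progeny trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection in polycross progeny trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycrossGS)
```

## The problem

In a polycross (PX) mating design, each maternal parent is pollinated with a
pooled mix of known pollen donors. Paternity is unknown a priori, so a
traditional analysis must treat each maternal family as pure half-sibs — an
assumption that is wrong in practice for three reasons: pollen donors
contribute unequally (creating hidden full-sib groups within maternal
families), pollen from outside the mix contaminates crosses, and operational
errors corrupt the maternal records themselves (mislabeled ramets, and even
mothers represented in the field by two distinct genotypes). Dense SNP
genotyping resolves all of this at once: the realized genomic relationship
matrix recovers the true pedigree, and genomic BLUP (GBLUP) exploits both
the corrected structure and within-family Mendelian sampling.

`polycrossGS` implements this workflow end to end: marker QC and
relationship matrices, relationship-based pedigree reconstruction,
individual-tree mixed models fitted by average-information REML, and
selection-gain/diversity accounting — together with a polycross trial
simulator that provides ground truth for every stage.

## Relationship matrices

Four kernels drive the models.

* **Realized additive (`G_additive`)**: VanRaden's first method,
  $G = WW' / (2\sum_m p_m(1-p_m))$ with $W$ the dosage matrix column-centered
  at $2p_m$. Allele frequencies are computed from the analyzed sample
  (parents and offspring jointly); no external base frequencies are assumed.
  A consequence worth knowing: average relationship in the analyzed sample is
  forced toward zero, so when the sample is dominated by close relatives the
  class means sit slightly below their pedigree expectations (half-sib pairs
  realize near 0.21–0.25 rather than exactly 0.25). This is a property of the
  estimator, not a simulator bias, and it matches what realized-relationship
  histograms show in practice.
* **Realized dominance (`G_dominance`)**: Vitezica's coding
  ($-2q^2,\, 2pq,\, -2p^2$ for dosages 0, 1, 2), mean-zero under
  Hardy–Weinberg proportions, scaled by $\sum_m (2p_mq_m)^2$. Fractional
  imputed dosages enter by linear interpolation of the three-point coding.
* **Pedigree additive (`A_additive`)**: the tabular recursion
  $a_{ii} = 1 + 0.5\,a_{fm}$, $a_{ij} = 0.5(a_{jf} + a_{jm})$.
* **Pedigree dominance (`A_dominance`)**:
  $d_{ij} = 0.25(a_{f_if_j}a_{m_im_j} + a_{f_im_j}a_{m_if_j})$, diagonal 1.
  This product form is exact for outbred individuals whose parents are not
  themselves inbred; the test suite verifies it against a gene-dropping
  Monte Carlo oracle on exactly those configurations.

QC before matrix building follows the usual two-pass rule: individuals above
a missingness ceiling are dropped first (default 40%), then SNPs failing the
minor-allele-frequency floor (default 1%) or the per-SNP missingness ceiling
(default 20%) are removed, and frequencies are recomputed from the retained
data. Missing calls are imputed either by the per-SNP mean (`2p`, the
default: at the sub-percent missingness typical of filtered capture panels
the choice is immaterial, which a property test asserts) or by an iterated
low-rank conditional-mean scheme (`method = "em"`) that exploits relatedness
structure and measurably beats mean imputation at 5% missingness.

## Pedigree reconstruction

Reconstruction uses only the realized relationship matrix and two
thresholds: 0.15 for accepting a parent–offspring link and 0.07 for
half-sib cohesion, with configurable cutoffs of 0.80 for duplicates and
0.70 for selfs. The stages run in a fixed order — duplicates, maternity,
family splits, paternity, selfs, contribution test — each consuming the
previous stage's output:

1. **Duplicates**: all pairs at or above 0.80; the member with more missing
   genotype calls is flagged for removal. The default sits midway between
   the full-sib expectation (0.5) and empirically observed re-genotyped
   duplicates (≈0.9).
2. **Maternity**: each offspring is assigned the genotyped female with the
   maximal relationship, accepted at 0.15; disagreement with the record is a
   pedigree error. Ties break to the lowest-sorting id with a warning.
3. **Family splits**: within a recorded family, offspring unrelated to the
   genotyped mother form a candidate hidden-mother group. A split is declared
   only when both groups have at least 5 members and the unrelated group is
   internally cohesive at the half-sib level — mean pairwise relationship at
   or above 0.07 with at most 20% of pairs below it, i.e. the within-group
   relationship histogram has lost its peak at zero. The hidden mother enters
   the corrected pedigree as a new founder (`<id>_B`). The 20% impurity
   allowance and minimum group size operationalize a visual histogram
   diagnosis; both are configurable.
4. **Paternity**: argmax over candidate males at 0.15, then a confirmation
   pass demotes members whose mean relationship to their assembled paternal
   half-sib family falls below 0.07 (using the mean rather than the minimum:
   a single noisy pair should not expel a true sib). Offspring without a
   qualifying father are pollen contaminants.
5. **Selfs**: relationship to the confirmed mother at or above 0.70 with no
   distinct qualifying father. A self of a *non-genotyped* (hidden) mother is
   indistinguishable from a contaminant without her genotype and is reported
   in the contaminant class — the same lumping used when such trees are
   scored in practice.
6. **Contribution test**: a chi-squared test of the realized per-donor
   offspring counts (contaminants and selfs excluded) against the equal
   expectation total/k, with k−1 degrees of freedom.

On simulated study-scale trials (26 mothers × 21 donors, 2000 SNPs, 12%
mislabels, 8 dual-genotype mothers, 5% contamination) the suite requires
≥99% paternity accuracy, ≥99% mislabel correction, every injected split
detected, and ≥95% contaminant recall.

## The individual-tree model

For each trait the package fits
$$y = X\beta + Z_1 rs + Z_2 ibr + Z_3 a + Z_4 sa \;(+ Z_5 d + Z_6 sd) + e$$
with site means (plus optional covariates such as ring count and heartwood
width for wood traits) fixed; replicate-within-site and set-within-replicate
random; additive and dominance effects with covariance
$\sigma^2_a K_a$ and $\sigma^2_d K_d$ for any of the four kernels; and a
heterogeneous residual with one variance per site. Traits flagged lognormal
are log-transformed before modeling.

**Site interactions.** The site-by-genetic terms are modeled as an
independent kernel-distributed realization per site: the interaction
covariance between trees $i, j$ is $\sigma^2_{sa} K_{ij}$ if they share a
site and zero otherwise. With single-tree plots this block structure is
equivalent to the usual main-plus-interaction compound parameterization and
keeps every covariance term linear in its parameter.

**Estimation.** All structures are linear in the variance parameters, so one
engine maximizes the restricted likelihood for every model: average-
information updates with step-halving, an active-set treatment that freezes
components pinned at the boundary with downhill gradients (without it the
Newton steps zigzag near a boundary optimum), and an EM-style fallback, so
the log-likelihood never decreases. Negative proposals for variance
components are clamped at a floor of $10^{-8}\times$ the phenotypic variance
and flagged as boundary estimates — kept positive so that downstream
accuracy formulas stay defined, mirroring how boundary components are
reported as zero-with-no-SE in practice. Convergence requires a relative
log-likelihood change below $10^{-8}$ and relative parameter change below
$10^{-6}$ (at most 200 iterations). The engine reproduces the closed-form
balanced half-sib REML estimator to machine precision, and BLUPs and their
standard errors match an independent Henderson mixed-model-equation solve in
the test suite.

**Derived parameters.** With $\bar\sigma^2_e$ the unweighted mean of the
per-site residual variances (unweighted averaging reproduces the printed
heritabilities of the motivating analysis exactly, which a weighted mean
does not):

* narrow-sense $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{sa} + \sigma^2_d
  + \sigma^2_{sd} + \bar\sigma^2_e)$, dominance terms present only when the
  model includes them;
* broad-sense $H^2$ adds $\sigma^2_d$ to the numerator;
* type-B genetic correlation $r_B = \sigma^2_a/(\sigma^2_a +
  \sigma^2_{sa})$, equal to 1 when the interaction variance is zero;
* theoretical accuracy $\hat r_i = \sqrt{1 - SE_i^2/((1+F_i)\hat\sigma^2_a)}$
  with $1+F_i$ the kernel diagonal, clipped to $[0,1]$;
* standard errors by the first-order delta method on the AI-matrix inverse.
  Components held fixed (`constrained_components`, used to re-score pedigree
  models at genomic component values) contribute no sampling variance.

Component significance uses the likelihood-ratio test against
$\chi^2_1$, with the boundary-corrected
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture p-value reported alongside;
the plain $\chi^2_1$ value is the primary column because that is the
convention in the tree-breeding literature this package serves. AIC counts
only free, non-boundary variance parameters (fixed-effect structures are
identical across the compared models).

**Trait correlations.** Phenotypic correlations use adjusted phenotypes:
residuals from the model without its genetic terms. Genetic correlations
come from a bivariate REML fit with an unstructured 2×2 additive covariance
(three linear parameters, the cross-covariance unconstrained) and an
unstructured residual covariance per site; $r_g$ is clamped to $[-1,1]$ and
declared significant when $|r_g| \ge 2\,SE$. Pairwise bivariate fits replace
higher-order multivariate models deliberately: they carry the same scientific
content with far better-conditioned optimization. If a bivariate fit fails
to converge (e.g. at a perfect-correlation boundary) the correlation of
univariate breeding values is returned with a warning.

## Selection accounting

`select_top` takes the top fraction (default 5%) by breeding value, with
cutoff ties broken by id order and logged. Expected gain is the selected
mean BV as a percent of the population phenotypic mean on the modeling
scale; for log-modeled traits the log scale is primary and recorded.
Diversity uses the status number $N_s = 1/(2\theta)$, where the group
coancestry $\theta$ is the mean over all ordered pairs (self-pairs included)
of half the additive relationship; self-coancestry of a non-inbred tree is
0.5, so a set of $N$ unrelated trees has $N_s = N$, a single tree has
$N_s = 1$, and two full sibs have $\theta = 0.375$, $N_s = 4/3$. Pedigree-A
is the default relationship source. Cross-model correction re-scores one
model's selected set with a reference model's BVs (GBLUP-additive by
default, as the most reliable scorer) and reports corrected gain, percent
overlap with the reference selection, and percent overestimation.

## The trial simulator

`simulate_founders` draws unrelated, non-inbred founders in Hardy–Weinberg
proportions at per-SNP frequencies uniform on a configurable range (default
0.05–0.5). `simulate_polycross` mates them: each offspring's father is drawn
from the pollen-mix contribution weights — by default a symmetric
Dirichlet(1) draw, reproducing strong contribution skew; the paper trail
behind this package reports only the skewed outcome, not the generating law,
so the Dirichlet is a stand-in, with the concentration configurable — or
replaced by the mother (selfing) or a freshly simulated unrelated foreign
tree (contamination, never added to the candidate list). Gametes segregate
independently per SNP: the analysis uses genome-wide relatedness only, so
linkage adds cost without affecting any tested quantity. The recorded
pedigree then corrupts the truth: mislabels swap the recorded mother, and
each dual-genotype mother's hidden second genotype (an independent founder)
truly mothers a Uniform(0.3, 0.7) fraction of her family so both clusters
are sizeable. Defaults mirror the motivating trial: 26 mothers, 21 donors,
12% mislabels, 8/26 dual-genotype mothers, 5% contamination, 1% selfing,
three sites with single-tree plots in 5 replicates × 4 sets.

`simulate_phenotypes` draws every random term from its stated covariance —
additive and dominance effects from the marker-derived kernels of the true
genotypes (or pedigree kernels on request), site interactions independently
per site, heterogeneous residuals — and exponentiates lognormal traits
simulated on the log scale around log site means. Wood-trait covariates are
independent standard normals with user-set fixed coefficients.

What the simulator does *not* emulate: linkage disequilibrium and realistic
LD decay, selection or mutation history, spatial field trends, genotyping
error (beyond what users inject), and climate covariates. Passing tests
therefore demonstrate correctness of the estimators under the assumed
generating model, not robustness to every field reality.

## Problem sizes and numerical choices

The validation suite exercises the study's own scale where it matters:
variance-component recovery runs 10 replicates of a 26 × 21 trial with
~1500 offspring and 2000 SNPs (each true component within two reported
standard errors in ≥90% of component–replicate pairs), and pedigree
reconstruction is validated on one full-scale error-laden trial. Elsewhere
smaller configurations (5–10 families, 200–800 SNPs) keep individual tests
sharp and the whole suite under a few minutes. Kernels are jittered by
$10^{-8}$ on the diagonal only where a Cholesky factor or inverse is
required. The chi-squared contribution test is validated for calibration at
the null (rejection rate within [0.02, 0.08] at α = 0.05 over 500
multinomial replicates).

## Known limitations

* Likelihood-based parentage (LOD scores) and sibship reconstruction
  without genotyped parents are out of scope; reconstruction requires the
  candidate parents in the relationship matrix.
* The dominance pedigree matrix uses the standard product approximation,
  inexact under parental inbreeding/relatedness (the genomic `G_dominance`
  has no such restriction).
* Bivariate fits cover trait pairs; full multivariate covariance estimation
  is not provided.
* Read-depth, quality and allele-balance filters belong upstream: the
  package accepts a pre-filtered VCF and re-applies only MAF/missingness
  rules, since raw FORMAT fields carry no information used by the methods
  here.
* No optimal-contribution or diversity-constrained selection; gains are the
  unconstrained top-fraction maximum by design.
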