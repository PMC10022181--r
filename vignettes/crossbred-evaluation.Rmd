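---
title: "Single-step genomic evaluation for two-way crossbred performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation for two-way crossbred performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossblup)
```

# The problem

In two-way crossbreeding systems — here a beef sire breed (`B`) mated to a
dairy dam breed (`H`), producing F1 calves (`BH`) — the breeding goal is
crossbred performance, but selection candidates are purebreds, many of them
without genotypes or crossbred progeny records. Single-step GBLUP (ssGBLUP)
handles this by combining pedigree and marker information in one
relationship matrix `H`, so genotyped and non-genotyped animals are
evaluated jointly. Because the two parental breeds differ in allele
frequencies and linkage phase, `crossblup` implements three variants of the
relationship model inside one bivariate animal model
`y = Xb + Zu + e` (two traits of the feedlot test: growth rate and feed
conversion, both lowly heritable and negatively correlated):

* **Standard ssGBLUP** — one genetic term with the usual `H` built from the
  numerator relationship matrix `A` and the VanRaden genomic matrix
  `G = ZZ'/Σ2p_i q_i`, `G` adjusted to be compatible with `A` (intercept +
  slope matching of overall and diagonal means) and blended with `A22`
  using weight `ω`.
* **Metafounder ssGBLUP (MF)** — unknown founders are replaced by two
  pseudo-founders (one per breed) with self- and cross-relationships
  collected in the 2×2 matrix `Γ`; the pedigree side becomes `A^Γ` and the
  genomic side the 0.5-referenced matrix `G^0.5 = ZZ'/(m/2)`. `Γ` is
  estimated by generalised least squares from the genotyped purebreds:
  per marker, the base-population frequency of each breed is the GLS mean
  of half-dosages weighted by the inverse pedigree relationships, and
  `Γ = 8 S` with `S` the across-marker second-moment matrix of deviations
  from 0.5. Genetic variances estimated under related metafounders are
  rescaled by `k = 1 + mean(diag Γ)/2 − mean(Γ)` to the
  unrelated-founders scale; correlations are unaffected.
* **Breed-specific ssGBLUP (BS)** — two genetic terms, one per breed of
  allele origin, with partial pedigree matrices `A^(B)`, `A^(H)`
  (García-Cortés–Toro recursion; they sum to `A`) and partial genomic
  matrices built from breed-specific allele contents. The latter require
  assigning each crossbred haplotype to its breed of origin (below).

# Breed of origin of alleles

For F1 animals each chromosome copy descends unrecombined (with respect to
breed) from one parental breed, so assignment is per chromosome, not per
segment:

* **Parent rule** (used when a genotyped, phased parent exists): four
  allele-difference counts between the two crossbred haplotypes and the two
  parent haplotypes; the crossbred haplotype in the pair with the smallest
  count takes the parent's breed, the other haplotype the other breed.
* **Panel rule** (no genotyped parent): the chromosome is cut into
  non-overlapping 50-SNP windows; each crossbred segment counts exact
  copies of itself in each breed's phased reference panel and votes for the
  breed with more copies; the chromosome goes to the majority breed and the
  complementary breed is forced on the other haplotype.

Ties are resolved deterministically and flagged: in the parent rule by the
second-smallest counts (then haplotype 1 takes the parent's breed); in the
panel rule a double-majority conflict is settled by total copy counts. The
final short window (< 50 SNPs) votes like any other; a segment with no
copies in either panel abstains. Exact window matching is intentional —
at F1 granularity the within-breed haplotype mosaic is irrelevant, and a
mismatch tolerance would only blur the breed signal. The procedure is not
suitable for three-way or rotational crosses, where chromosomes are breed
mosaics.

# Mixed model, REML, and reliabilities

All fitting goes through dense Henderson mixed-model equations. Each
genetic term carries its own animal set: the breed-specific partial
matrices are structurally singular outside the animals carrying genome of
that breed, so the `B` term covers B purebreds plus crossbreds, and
likewise for `H`. Fixed effects (sex, pen, herd-year-season, start-weight
covariate) are estimated per trait; records missing one trait enter with
that animal's reduced residual block. Total crossbred EBV under the
breed-specific model are the sum of the two origin terms.

REML maximises the restricted likelihood of the observation-level
covariance, with relationship matrices collapsed to the phenotyped animals
(the marginal likelihood is identical, and the collapse keeps one fit at a
few seconds for cohorts of hundreds of animals). The default algorithm is
average-information (AI) scoring with step-halving; whenever an AI step
leaves the parameter space or fails to improve the likelihood, one EM step
is taken instead (EM never decreases the restricted likelihood, which the
test suite asserts on its trajectory). Convergence is declared on relative
parameter change (`tol`, default 1e-8) or on likelihood stagnation below
1e-9 per iteration; variances shrinking to zero are clamped at a floor of
1e-8 of the phenotypic variance and reported as boundary estimates.
Asymptotic standard errors come from the inverse AI matrix at convergence,
and heritability / genetic-correlation SEs from the first-order delta
method with numerical gradients. Starting values put 30% of the phenotypic
(co)variance on the genetic side — a deliberately modest share, since the
package's target traits are lowly heritable and large genetic starts make
early AI steps overshoot.

Model-based reliabilities use prediction error variances from the inverse
coefficient matrix. Standard: `Rel_i = 1 − PEV_ii/(H_ii σ²_u)`. Under
metafounders that definition underestimates reliability, so the package
reports contrasts to a reference metafounder,
`1 − [PEV(u_i) + PEV(u_mf) − 2 PEV(u_i, u_mf)] /
[(H_ii + H_mf,mf − 2 H_i,mf) σ²_u]`, one value per metafounder plus a
breed-fraction-weighted combination. For the breed-specific model the
published denominator names an `H_A` matrix without defining it; this
package interprets the combined reliability as
`1 − PEV(û_B,i + û_H,i)/(H_B,ii σ²_B + H_H,ii σ²_H)` — the natural
variance of the summed breeding value under independent origin terms — and
also emits the per-breed reliabilities, so users can apply a different
aggregation if they prefer.

# LR validation

Predictive ability is measured with the linear-regression (LR) method: the
data are split at a cut-off birth date (born strictly before = partial
dataset; on/after = focal animals), both evaluations are run, and four
estimators compare focal EBV: bias `Δ = mean(û_p) − mean(û_w)`, dispersion
`b = cov(û_w, û_p)/var(û_p)`, population accuracy
`acc = sqrt(cov(û_w, û_p)/((1 + F̄ − 2f̄) σ²_u))`, and the accuracy ratio
`ρ = cor(û_w, û_p)`, whose reciprocal minus one is the relative accuracy
gain from partial to whole information. Variance components are
re-estimated on the partial data by default (a flag reuses the whole-data
estimates), `σ²_u` in the accuracy denominator is the partial-fit genetic
variance — rescaled for MF, and the aggregate `0.5(σ²_B + σ²_H)` for BS,
the same aggregate the heritability uses — and `F̄`, `2f̄` come from the
pedigree of the focal animals. Sample covariances use the `n − 1`
convention. `run_lr(cutoff = NULL, focal = ...)` provides a no-holdout
control in which the estimators are exactly (0, 1, ·, 1).

# The simulator

`sim_config()` defaults encode the study conditions the package targets:
two purebred populations diverged at `fst = 0.15` (ancestral frequencies
uniform on (0.05, 0.95), breed frequencies Beta-distributed with variance
`fst·p(1−p)`), 5 chromosomes × 500 phased SNPs (one Morgan each, Poisson
crossovers, no interference), 50 sires × ~38 progeny against 2000 dams,
three purebred generations behind the parents, two traits with
heritability 0.08 each and genetic correlation −0.5, breed-origin marker
effects correlated 0.7, 70% of sires and 13% of dams genotyped, all
crossbreds genotyped, 11% of records missing the second trait, and birth
dates spread over a 2.5-year window. Residual variance is solved per
replicate from the realized TBV variance so the target heritability holds
exactly in expectation.

Choices the data could not pin down, made once: the residual correlation
between the traits is −0.3 (faster growth mechanically improves feed
conversion, so an environmentally negative correlation of moderate size is
the realistic middle ground); breed frequencies are clamped to
[0.05, 0.95] so the default panel stays segregating; fixed-effect levels
default to 2 sexes, 10 pens, 8 herd-year-seasons with effect SDs of
0.5/0.3/0.3 phenotypic SD and a start-weight slope of 0.3 SD per 25 kg.

What the simulator deliberately omits: linkage disequilibrium within
breeds beyond what three generations of gene dropping create (founder
haplotypes are sampled site-independently), selection, genotyping error,
and imputation error. Passing tests therefore demonstrate the estimators
and algorithms on data satisfying the model's assumptions — they do not
certify behaviour under model misspecification, historical LD, or the
imputation artefacts of real chip data (phased input is a precondition of
the package, not something it produces).

# Numerical choices and edge cases

* The single-step block formulas are evaluated densely; matrices here are
  at most tens of thousands on a side, and dense construction keeps PEV
  extraction and testing simple. Inverse-free sparse tricks are an
  optimisation, not part of any contract.
* In the published metafounder and breed-specific block formulas the
  bottom-right corner reads `(1−ω)G + ω A22⁻¹`; the inverse is treated as
  a typographical slip and `ω A22` is used, consistent with the standard
  formula and the sources both variants cite.
* The compatibility adjustment `G* = a + bG` can make a rank-deficient
  genomic matrix indefinite when `a < 0` (small reference panels); the
  blended matrix is therefore eigenvalue-bent back to PSD
  (`bend_psd()`, relative floor 1e-6). With healthy panels this is a no-op.
* Γ estimation centres the second moments at 0.5 — the reference frequency
  of `G^0.5` — rather than at per-marker means, and uses purebred
  genotypes only. Pooled frequencies over all genotyped animals feed the
  standard `G`; breed-specific frequencies (from genotyped purebreds of
  that breed) feed each `G^(b)`, whose markers monomorphic within the
  breed are excluded with a warning.
* Unknown parents: purebreds map to their own breed's metafounder; a
  crossbred with one known parent maps the missing one to the other
  breed; a crossbred with no known parents maps sire→B, dam→H (the
  production system's direction) under metafounders, and is a hard error
  for the breed-specific recursion, where its genome fractions would be
  undefined.
* Exactly duplicated phenotype rows are merged; genuinely repeated records
  per animal are rejected (the model has no permanent-environment term).
* HWE quality control uses a 1-df chi-square without continuity
  correction, within pure breeds only — testing Hardy-Weinberg in admixed
  F1s would be meaningless. Filter attribution follows the order
  individual call-rate, SNP call-rate, MAF (recomputed after individual
  removal), HWE; a marker is attributed to the first rule it fails.

# Problem sizes

The test suite and the reproduction script run the full pipeline on
reduced cohorts — typically 450–500 crossbreds for variance-component
recovery (20 replicates, standard and metafounder fits), ~500 crossbreds
with 13 genotyped sires for the tracing-accuracy check, and ~100 crossbreds
for the module-level pipeline tests. These sizes keep a full dense REML fit
at a few seconds while leaving the estimators' sampling error small enough
for two-standard-error checks; the simulator's defaults remain at the
full study scale and can be run directly for larger experiments.

# Limitations

Two pure breeds and F1 crossbreds only; no imputation or phasing; no
maternal, permanent-environment, or genotype-by-environment terms; at most
two traits; dense algebra limits routine use to pedigrees of a few tens of
thousands. The LR accuracy estimator inherits the usual caveat that it is
only as good as the variance components plugged into its denominator.
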