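---
title: "Multi-line single-step genomic evaluation: models, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-line single-step genomic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pig breeding programs evaluate several purebred lines, and crossbred
descendants of those lines, in one genetic evaluation.  Single-step genomic
BLUP (ssGBLUP) joins three information sources — pedigree, genotypes, and
phenotypes — through a combined relationship matrix `H`, whose inverse enters
the mixed-model equations directly:

    H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]

where `A` is the pedigree (numerator) relationship matrix, `A22` its
restriction to genotyped animals, and `G` the genomic relationship matrix.
When lines with different genetic bases are evaluated jointly, animals with
unknown parents cannot all be treated as draws from one base population.
This package implements the two standard remedies and the machinery around
them:

* **Unknown-parent groups (UPG)**: missing parents are assigned to groups by
  line of origin; group effects `g` enter the model through the expected
  base-contribution matrix `Q`, and the pedigree inverse becomes the
  Quaas-Pollak transformed `A* = [A^-1, -A^-1 Q; -Q'A^-1, Q'A^-1 Q]`.
  Two flavors differ in whether the genomic term also carries group
  structure (UPG1) or not (UPG2).
* **Metafounders (MF)**: one pseudo-founder per base population, allowed to
  be related and inbred through a matrix `Gamma` estimated from markers;
  `A(Gamma)` follows from the ordinary tabular recursion over the augmented
  pedigree, paired with a `G` centered at allele frequency 0.5.

Around the core sit the standard supporting steps: VanRaden method-1 `G`
(optionally SNP-weighted, blended with 5% `A22` against singularity), the
APY sparse inverse with eigenvalue-based core sizing, genotype quality
control, GWAS-windowed variant preselection panels, a BayesR sampler whose
posterior SNP variances become weights, and LR-method validation.

## Model

For traits `y` (e.g. growth and backfat, with crossbred expressions treated
as separate traits):

    y = X b + W c + Z u + Z Q g + e

with fixed effects `b` (contemporary groups, covariates), random litter
effects `c`, additive effects `u`, and — for UPG flavors — group effects
`g`.  Variance components are inputs, as in routine evaluation.  Multi-trait
systems use `G0^-1 (x) H^-1` Kronecker penalties, and records missing a
trait contribute through the inverse of the residual covariance restricted
to their observed traits (this carries the crossbred-only traits).

**Coordinates for UPG solutions.** The block operators above are usually
printed in "total" coordinates `(u + Qg, g)`, in which records load only on
animal equations.  The model equation, however, is written with `ZQg` in the
design and reports `GEBV = Qg + u`.  These are the same model in two
coordinate systems, related by the congruence transform `S = [I, Q; 0, I]`.
The package assembles the printed operator in `build_hinv()` (so its blocks
can be verified against the literature) and re-expresses it as `S' H* S`
inside `assemble_mme()`, so that the reported animal solutions are
deviations and `GEBV = Qg + u` holds exactly.  A consequence verified in the
tests: for UPG1, `S' H* S` collapses to the standard `H^-1` padded with a
zero group block — the group equations are informed only through the `ZQ`
design columns.

**Group identifiability.** With groups defined by line of origin and
contemporary groups nested in line, group effects are confounded with the
per-line intercepts.  A scaled ridge (1e-8 of the largest coefficient
diagonal) on the group equations makes the system determinate; GEBV are
insensitive to it at far below test tolerances.  When fixed effects are
shared across lines (as in the joint multi-line setting the groups are for),
the group solutions absorb genuine base differences, which is the behavior
the tests exercise.

**UPG2 block signs.** The UPG2 operator is assembled as

    A* + [G^-1 - A22^-1,  A22^-1 Q2;  Q2' A22^-1,  -Q2' A22^-1 Q2]

i.e. the Quaas-Pollak decomposition in which the pedigree terms (`A`, `A22`)
carry group structure and the genomic term acts on totals.  The defining
quadratic form — pedigree deviations plus genomic totals minus genotyped
pedigree deviations — is asserted directly in the test suite.  Note that
UPG1 and UPG2 remain different models even when `G = A22`: UPG1 then
collapses exactly to `A*`, while UPG2 keeps its genomic-total terms.

## Relationship operators

* `A^-1` by Henderson's rules with Meuwissen-Luo inbreeding (the method is
  validated against the tabular recursion, which the test suite implements
  independently).  Unknown parents in the plain setting contribute as
  unrelated, non-inbred base animals.
* `A22` exactly, by Colleau's indirect method (`A e_j` products through the
  `T D T'` factorisation) — no approximation, linear memory.
* `Gamma` by per-group generalized least squares: for each group, the base
  allele frequency of every marker is `(1'A22g^-1 1)^-1 1'A22g^-1 m/2` over
  that group's genotyped animals; `Gamma = 8 x` the across-marker covariance
  of these estimates.  Deviations are taken around 0.5 — the metafounder
  reference frequency that the 0.5-centered `G` pairs with; sample-mean
  centering is available as an option (`center = "mean"`).
* `A(Gamma)` by the tabular recursion over the metafounder-augmented
  pedigree (dense, desk scale); its sparse inverse by Henderson rules with
  the dense `Gamma^-1` founder block and Mendelian variances
  `1 - (a_ss + a_dd)/4`, so metafounder self-relationships propagate.
* `G` by VanRaden method 1, observed-frequency or 0.5-centered; residual
  missing dosages mean-imputed (centered value zero); blending
  `(1-beta) G + beta A22` with `beta = 0.05` applied to the full matrix
  before any APY partitioning (a per-block variant is deliberately out of
  scope at desk scale).
* APY: core size from the smallest number of leading eigenvalues explaining
  98% of the variation in the chip-panel `G`; core membership sampled
  uniformly within line with largest-remainder rounding of the per-line
  proportions, under a caller-supplied seed.

## The population simulator

The study data the methods were designed for are proprietary, so the package
carries a generator that emulates their statistical structure and is itself
tested code:

* 3+ purebred lines diverged from a shared ancestral population.  Ancestral
  frequencies are Uniform(0.05, 0.95); line-specific base frequencies follow
  the Balding-Nichols construction `Beta(p(1-F)/F, (1-p)(1-F)/F)` with drift
  `F = 0.1`, which yields an analytic "true Gamma" (computed from realized
  founder frequencies) and reproduces, qualitatively, positive
  between-group relationships and PCA line separation.
* Founder haplotypes come from a Gaussian-copula AR(1) process: a latent
  chain with correlation `exp(-d / 1 Mb)` between positions `d` apart,
  thresholded at each marker's base-frequency quantile.  This gives the
  long-range base LD of closed nucleus lines, under which a chip-density
  panel captures most of the additive variance of common causal variants —
  the regime in which ssGBLUP is approximately correctly specified.  The
  simulated genome is physically compressed (10 chromosomes x 7.5 Mb at
  15 kb marker spacing), so the genetic map rate is scaled up (10 cM/Mb) to
  keep per-chromosome map lengths realistic (~0.75 Morgan).
* Gene dropping uses Haldane recombination along each chromosome and free
  recombination across chromosomes.
* 100 QTL are drawn from WGS markers with pooled founder MAF >= 0.1 and
  excluded from the chip, so preselection panels have something real to
  find.  QTL effects are normal; the scaling anchors the mean within-line
  founder TBV variance at `sigma2_u = h2 * sigma2_p` (between-line
  divergence is on top of, not inside, the base variance).
* Phenotypes: contemporary group (line x generation, effects drawn once
  with SD 0.5) + litter (share 0.1) + additive (h2 = 0.3) + residual;
  crossbred cohorts, when configured, record only the crossbred trait,
  genetically correlated 0.7 with its purebred counterpart.
* Genotyping is selective: 60% of the last two generations, mirroring the
  fact that genotyped validation cohorts are a minority of their
  contemporary groups (whose other members keep phenotypes in a reduced
  run).  3% of recorded parent slots are masked as unknown — the true
  parent still transmits genotypes — which gives the UPG/MF machinery
  something to model.

What the simulator does **not** emulate: sequence-level data (read depth,
imputation error), selection (available only as future work; the default is
random mating, which the LR calibration expectations require), variable
genome density, dominance, and genotype-by-environment structure.  Passing
tests therefore demonstrate internal consistency of the machinery under the
stated statistical structure, not performance on any particular real
population.

## Validation

`make_split()` builds the forward split: test animals are genotyped members
of last-generation litters with at least five full sibs ("last generation" =
maximum birth year; the simulator emits one cohort per year); training
animals are the remaining genotyped animals whose largest pedigree
relationship with any test animal is strictly below 0.5.  `lr_statistics()`
computes, over validation animals,

* accuracy `sqrt(cov(u_w, u_r) / ((1 - Fbar) sigma2_u))`,
* standardized bias `(mean(u_r) - mean(u_w)) / sigma_u` (expectation 0),
* dispersion `b1 = cov(u_w, u_r) / var(u_r)` (expectation 1),

where `u_w`/`u_r` are GEBV from the whole data and from the data with
validation phenotypes removed (phenotype truncation only — genotypes stay).
A negative whole/reduced covariance is reported as zero accuracy with a
flag.  The accuracy formula assumes the within-base genetic variance, so
per-line reports (`lr_report_by_line()`) are the meaningful ones in
multi-line settings; the pooled report is also produced.  The standardising
`sigma2_u` is the configured component (a per-line component can be passed
instead).

## Numerical choices

* Mixed-model systems solve by sparse Cholesky (LDL, permuted); unknowns
  with empty equations (fixed-effect levels whose records were all removed)
  are constrained to zero; a Jacobi-preconditioned conjugate-gradient
  solver (tolerance 1e-10) is the fallback and the cross-check.
* Problem sizes: the calibration study uses 3 lines x 2,000 animals with
  1,000 chip markers and ~1,600 genotyped animals per replicate; oracle
  equivalences run on pedigrees of 90-500 animals; Gamma recovery uses
  5,000 WGS markers over a 3-line population of ~900 animals.  These sizes
  were chosen so each analysis states its question at full statistical
  structure while any single run stays interactive.
* BayesR: canonical variance fractions (0, 1e-4, 1e-3, 1e-2) of a fixed
  total additive variance; symmetric Dirichlet(1) prior on proportions;
  residual variance by scaled inverse chi-square; R's RNG throughout, so
  chains are exactly reproducible under a seed.  Under pure-noise data the
  zero and 1e-4 classes are statistically indistinguishable (the Occam
  factor cancels the expected likelihood gain exactly), so null behavior is
  assessed on the combined negligible-variance mass, not the zero class
  alone.  Weights floor at 1e-8 before rescaling to trace m.
* Windowed panel selection anchors 55-kb half-open windows at bp 0 per
  chromosome; ties on p break to the lowest position.  LD pruning is greedy
  left-to-right within a 1-Mb trailing window.
* Pedigree truncation by birth year re-founds animals whose parents were
  removed; this is one interpretation of cutting deep pedigrees before
  base-parameter estimation and is flagged as such in the function
  documentation.

## Known limitations

* Dense `A(Gamma)` construction bounds the MF flavor to desk-scale
  pedigrees (tens of thousands of animals).
* The GWAS used for preselection is a stand-in single-marker scan on
  adjusted phenotypes with a line covariate; claims about the panel
  machinery concern the selection rules, not GWAS power fidelity.
* Evaluating with markers that are not the causal variants leaves a small
  residual overdispersion (the model treats `G`'s deviations as exactly
  informative about QTL deviations); with the default tagging structure the
  replicate-mean dispersion sits within a few percent of 1, and an oracle
  run with `G` built from the true QTL is calibrated almost exactly.
* Variance components are never estimated; they are inputs, and the
  simulator writes its true components into the model specification it
  emits.
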