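---
title: "Random-regression evaluation of group- and individual-level feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-regression evaluation of group- and individual-level feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Feed intake (FI) of growing pigs is expensive to record per animal: single-
animal electronic feeders exist mainly at central test stations. On
production and nucleus farms, pigs share a feeder between pens, so intake is
naturally observed per *feeding group* — the total feed delivered to the
group over a recording period, divided by the period length. Group- and
individual-level FI are recorded in different environments with different
feeding systems, so they need not be the same trait genetically: the genetic
correlation between them, and the gain in prediction accuracy from combining
the two data sources, are the quantities of interest.

`penfeed` implements a bivariate random-regression ("test-day") evaluation
that treats group-level and individual-level daily FI as two traits, plus
the surrounding machinery: a synthetic-data generator reproducing the
recording structure, pedigree/genomic/single-step relationship matrices,
AI-REML variance-component estimation, per-day heritability and genetic-
correlation trajectories, and leave-one-group-out validation.

## The model

Days on test $t$ are mapped to $x \in [-1, 1]$ and plain (unnormalised)
Legendre polynomials $P_k(x)$ form the time covariates $\phi(t)$, with the
intercept covariate fixed at 1. For a group record (group $j$, day $t$):

$$y_{jt} = YM_l + \sum_{k=0}^{1} \bar w_j^k \beta_{k(m)} +
  \sum_{k=0}^{nf} \phi_k(t) b_{k(j^*m)} +
  \sum_{i=1}^{n_{jt}} \sum_{k=0}^{nr} \phi_k(t) a_{ik} +
  \sum_{k=0}^{np} \phi_k(t) pe_{jk} + e_{jt},$$

i.e. the record sums the genetic curves of the $n_{jt}$ animals present,
with fixed effects for start year–month, a class-specific intercept and
start-weight regression, and Legendre regressions nested in group-size ×
recording-class cells. Individual records carry the analogous single-animal
equation with un-nested fixed regressions. The genetic coefficients
(first-order for the group trait, second-order for the individual trait)
are stacked per animal as $[a^g_0, a^g_1, a^i_0, a^i_1, a^i_2]$ with
covariance $\mathbf G \otimes \mathbf K$, where $\mathbf K$ is the pedigree
matrix $\mathbf A$ (PBLUP) or the combined pedigree–genomic matrix
$\mathbf H$ (ssGBLUP). Permanent-environment coefficients use
$\mathbf I_p \otimes \mathbf P_1$ (one pair per feeding group) and
$\mathbf I_q \otimes \mathbf P_2$ (one triple per recorded animal).
Residuals are diagonal: a group record has variance
$(n_t/n_d)\,\sigma^2_e$ — it averages $n_t$ animals over $n_d$ days — and
individual records fall into eight days-on-test classes
($\le 10, 11\!-\!20, \dots, \ge 71$) with separate variances.

Per-day genetic variance is the covariance function
$\sigma^2_a(t) = \phi(t)\, \mathbf G_\text{trait}\, \phi(t)'$, the same for
permanent environment; heritability divides by the sum of the three
sources. The daily genetic correlation between the traits is
$r_t = \phi_{t2} \mathbf G_{12} \phi_{t1}' / \sqrt{\phi_{t1}\mathbf
G_1\phi_{t1}'}\sqrt{\phi_{t2}\mathbf G_2\phi_{t2}'}$ and the whole-period
correlation replaces $\phi_t$ by the column sums $\phi^*$ of the daily
covariate matrices — the correlation of test-period-summed breeding values.

## Estimation

Variance components are estimated by average-information REML on the full
parameter vector (all distinct elements of $\mathbf G$, $\mathbf P_1$,
$\mathbf P_2$, and the residual class variances):

* The mixed-model equations are assembled sparsely; each iteration reuses a
  precomputed pattern template and refactorises with CHOLMOD.
* Exact gradients use the trace identities that require selected entries of
  the inverse coefficient matrix; these are computed with a Takahashi
  selected inversion of the simplicial Cholesky factor (the approach of the
  established REML programs for animal breeding).
* The AI matrix is built from working vectors, one extra multi-right-hand-
  side solve per iteration.
* Step halving enforces a non-decreasing restricted likelihood; when the AI
  direction fails (far from the optimum, or on the boundary of the
  parameter cone) the iteration falls back to the EM-REML update, which is
  monotone and stays inside the cone. The first two iterations always use
  EM to stabilise the path from rough starting values.

Numerical choices that matter:

* *Starting values*: 10% genetic / 10% permanent environment / 80% residual
  of each trait's detrended phenotypic variance, zero covariances. For the
  group residual variance the start is a method-of-moments estimate:
  within-group second moments are regressed on the quadratic basis terms
  and the $n_t/n_d$ weights across groups, which is precisely the contrast
  that separates the residual from the shared group curves.
* *Boundaries*: covariance blocks are kept positive semi-definite by
  eigenvalue flooring at $10^{-6}$ of the trace; residual variances are
  bounded below at $10^{-5}$ of their class data variance. The latter is a
  conditioning bound: the restricted likelihood cannot be evaluated
  reliably once a variance ratio exceeds about $10^{8}$, and an optimizer
  allowed into that regime chases rounding noise. One step of iterative
  refinement is applied to every solve for the same reason.
* *Convergence*: gradient norm below `grad_tol` (default `1e-4`), with a
  secondary stop on relative parameter change; the `converged` flag is
  only set when the first-order condition holds.

### Identifiability of the group-level components

With exactly two records per group and a first-order group-level
permanent-environment curve, the within-group 2×2 covariance is
$\Phi_g \mathbf P_1 \Phi_g' + \sigma^2_e D_g$, which is over-parameterised
when the recording days and weights $D_g$ are identical across groups: the
likelihood then has a flat ridge trading $\sigma^2_e$ against $\mathbf P_1$
(and partly against the group genetic variance), and the maximum drifts to
a boundary. Identification comes only from between-group variation in the
recording days ("approximately" day 30 and 60) and in $n_t/n_d$, and from
cross-group kinship. This is a property of the model, not of the
implementation — we verified that an independent dense-likelihood optimiser
lands on the same ridge — and it mirrors the instability of group-level
residual-variance estimates reported for field data of this design. The
simulator therefore draws per-group recording days with a ±5-day jitter and
uses a few-sires mating structure, both realistic, which makes the
group-side components weakly but genuinely identified. Expect their
single-replicate estimates to be noisy; the individual-side components and
the correlation functionals are well identified.

## The simulator

`sim_config()` + `simulate_population()` generate: founders and two
descendant generations (a small parent generation and a large phenotyped
one; `n_sires` boars in service per generation give the half-sib structure
of a nucleus herd); unlinked SNPs gene-dropped through the pedigree;
genetic coefficients either transmitted through the pedigree (parent
average plus inbreeding-scaled Mendelian sampling, exactly
$\mathbf A \otimes \mathbf G$) or built from additive SNP effects
(`coef_from_snps = TRUE`, which makes genomic relationships causal and is
used when demonstrating ssGBLUP gains); weight-sorted pens of 10 with two
pens per feeder; pre-test removals and period-boundary drop-outs; pooled
group records at two jittered time points (records literally accumulate
daily residual draws, so the $n_t/n_d$ law holds by construction); and
daily individual records over 75 (default) or 60 days with the 8-class
residual structure.

Default calibration follows the scale of DanBred-type growing-pig data:
mean daily genetic variance ≈ 0.17 (group) / 0.10 (individual), permanent
environment ≈ 0.08, residuals 1.94 (group, animal-day scale) and ≈ 0.21
(individual mean), mean daily intake rising 1.5 → 3.4 kg/d, whole-period
genetic correlation 0.3 (the cross-block loading is solved exactly against
the period-correlation formula).

What the generator does *not* emulate: feeder mechanics (refills, wastage),
visit-level behaviour (beyond a daily-sum helper), indirect genetic
effects, selection, and linkage disequilibrium. Passing tests therefore
show that the estimation machinery recovers the parameters of data that
satisfy the model's assumptions — not that field data do.

## Validation

`run_logo_cv()` removes each feeding group's records in turn and re-solves
with the pre-estimated full-data variance components. Each fold is obtained
exactly by a rank-two Woodbury downdate of the full factorisation (two
triangular solves per fold), verified against direct refits. Statistics:
correlation and regression slope of full- on reduced-data period (G)EBV per
animal (overall / genotyped / non-genotyped), the same between corrected
phenotypes $y_c$ (summed member EBV plus record residual, from the full
fit) and reduced-data group EBV, and per-group absolute full-vs-reduced
differences. The period EBV sums daily $\phi(t)\hat a_i$ over the two
recorded mid-point days of the animal's own group.

## Design choices made where the design was open

* Plain (unnormalised) Legendre polynomials, because the intercept
  covariate is fixed at 1.
* Group-trait permanent environment at the feeding-group level (one
  coefficient pair per group): per-animal coefficients summed within a
  group are not separately identifiable; a config switch
  (`pe_group_level = "animal"`) emits the summed-incidence variant.
* The two group recording classes share one homogeneous residual variance;
  a flag enables two classes.
* Class-specific weight regression read as a first-order weight polynomial:
  class intercept plus class slope.
* $\mathbf H^{-1}$ uses blending weight 0.05 on $\mathbf A_{22}$ with
  mean-diagonal/off-diagonal tuning of $\mathbf G$; unknown parents are
  treated as founders (no metafounders).
* Basis ranges default to the observed day span per trait; group-trait
  grids cover the jittered mid-point range, individual grids days 1 to the
  test length; the common grid for $r_t$ is the intersection.
* Whole-period correlations weight days equally (column sums), not by
  record counts.
* Corrected phenotypes use full-data residuals; folds re-use full-data
  variance components (they are not re-estimated per fold).
* Standard-error bands for trajectories are Monte-Carlo: parameter draws
  from the asymptotic normal implied by the inverse AI matrix, projected
  onto the cone, functional recomputed per draw.

## Problem sizes used by the test suite

The replicated checks run 10 simulation replicates of the default design
(60 groups × ~20 animals, 800 individual animals over 60 days, 50%
genotyped), with AI-REML capped at 15 iterations from warm starts and
leave-one-group-out validation under univariate-PBLUP, bivariate-PBLUP and
bivariate-ssGBLUP on each replicate. These sizes are the package's choice
of a desk-scale experiment that still exhibits the structure of the field
design; the dense-oracle and Monte-Carlo checks use small instances where
exact or near-exact agreement is asserted.

## Known limitations

* The group-side components ($\sigma^2_{e}$, $\mathbf P_1$) are weakly
  identified at two recording points per group (see above); their estimates
  should be read jointly, not separately.
* The AI-REML driver targets desk-scale problems (up to a few thousand
  animals); no iterative solvers or APY-style approximations are provided.
* Unknown-parent groups, genetic groups and indirect genetic effects are
  out of scope; the group-trait genetic effect absorbs any indirect
  effects, as in the source design.

## A minimal session

```{r example}
library(penfeed)

cfg <- sim_config(n_founders = 80, n_sires = 12,
                  offspring_per_mating = c(4, 10),
                  n_ind_animals = 200, n_snps = 500,
                  ind_test_length_days = 60)
sim <- simulate_population(cfg, seed = 1)

spec <- model_spec("bivariate")
des <- build_design(sim, spec, basis_grp = cfg$basis_grp,
                    basis_ind = cfg$basis_ind)
Kinv <- ainverse(sim$pedigree)
fit <- ai_reml(des, Kinv)
tidy(fit)
glance(fit)

h2 <- heritability_trajectory(fit$vc, "individual", cfg$basis_ind,
                              cfg$days_ind)
autoplot(h2)
period_genetic_correlation(fit$vc, cfg$basis_grp, cfg$basis_ind,
                           cfg$days_grp, cfg$days_ind)

cv <- run_logo_cv(sim, fit$vc, spec, Kinv,
                  basis_grp = cfg$basis_grp, basis_ind = cfg$basis_ind)
cv$stats
```
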