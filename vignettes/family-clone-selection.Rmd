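---
title: "Family-aware mixed models for early-stage clonal selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-aware mixed models for early-stage clonal selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the first field stage of a tetraploid potato breeding program,
thousands of unreplicated clones descending from biparental (full-sib)
families are screened in augmented block designs (ABD, checks replicated
once per block) or partially replicated designs (P-REP, a fraction
`p_N` of plots carrying a second replicate of some entries). Seed-tuber
scarcity keeps replication minimal, so the accuracy of clonal selection
is low precisely at the stage where most candidates are discarded.

Clones arrive with a pedigree structure that costs nothing to record:
every clone belongs to a family. `famclone` implements and evaluates the
modelling consequence — treating the genotypic value of a clone as the
sum of a family effect and a clone-within-family effect — for
single-trial (ST) and multi-environment-trial (MET) analysis, including
seasons that differ in heat-stress load.

## The model

All analyses use one linear mixed model,

y = 1 mu + X_o tau_o + Z_s u_s + Z_c u_c + Z_b u_b + e,

with `tau_o` the fixed check effects (plus environment and
check-by-environment effects in MET), `u_s` the random family effects,
`u_c` the random clone-within-family effects, `u_b` the random block
effects and `e` the residual. Check plots carry no genetic random
effect; the intercept is the clone population mean and each check gets
its own fixed coefficient, which keeps the fixed design full rank.

Four named variants are fitted by `famclone()`:

* `STMpF` — one trial, family + clone-within-family, each with a single
  variance (`sigma2_s`, `sigma2_c`), block and residual variances.
* `STMwF` — one trial, no family term; the clone variance `sigma2_c'`
  then absorbs both genetic components (the confounding the package
  quantifies).
* `METMpF` — several trials analysed jointly in one stage; block and
  residual variances are heterogeneous per trial (direct sums) and the
  family and clone effects of each level across the t trials follow
  unstructured t x t covariance matrices `G_ts`, `G_tc` (so the
  covariance of each term is `G_t` Kronecker `I`, columns ordered
  trial-major). Each unstructured matrix carries t(t+1)/2 free
  parameters.
* `METMwF` — as `METMpF` without the family term.

The total genotypic value of a clone is the sum of its family BLUP and
its clone BLUP — per trial in MET, so it capitalises on
genotype-by-environment interaction. Under the nested model this sum has
a compound-symmetry covariance within families: `sigma2_s` is shared by
siblings, `sigma2_c` is clone specific, and
`rho_S = sigma2_s / (sigma2_s + sigma2_c)` measures the family share of
the genetic variance.

## Estimation

Variance components are estimated by REML, maximised with a
quasi-Newton search on transformed parameters: log variances, and the
log-Cholesky factor of each unstructured matrix, so every iterate is a
valid covariance configuration. The likelihood is evaluated through
Henderson's mixed-model equations with sparse matrices; the sparsity
pattern of the coefficient matrix is fixed, so each evaluation reduces
to a scatter-add of precomputed crossproducts and one numeric Cholesky
factorisation reusing the symbolic analysis. The reported
log-likelihood includes the constant `-(N - o)/2 log(2*pi)` (the same
convention lme4 uses), so AIC = -2 l + 2 p is internally consistent,
with `p` counting only covariance parameters; log-likelihoods from
other software may differ by a constant.

Numerical choices worth knowing:

* Starting values split half the phenotypic variance equally among the
  random terms; unstructured matrices start at identity scale.
  Convergence uses a relative log-likelihood tolerance of 1e-8, with a
  short Newton polish (central differences) for small parameter counts,
  which brings balanced-design estimates to within 1e-6 of their
  closed-form ANOVA values.
* Variances collapsing toward zero are reported as 0 with a boundary
  flag; the mixed-model equations are then solved at a tiny positive
  floor (1e-7 of the phenotypic variance).
* BLUPs and fixed effects come from the factorised mixed-model
  equations; prediction error variances (PEV) are diagonal entries of
  the inverse coefficient matrix. The PEV of the total genotypic value
  uses the joint block var(s_hat + c_hat - (s + c)) — including the PEV
  covariance between the family and clone predictors — because the
  accuracy formula for the total effect divides by
  `sigma2_s + sigma2_c`. Averages of per-level PEVs feed the
  accuracies r = sqrt(1 - v / sigma2), and the relative efficiency of
  total-genotypic over clone-only selection is RE = r_g / r_c. MET
  accuracies are per trial, from that trial's diagonal entries; averages
  over seasons are arithmetic means.
* Missing plot values are dropped row-wise; the one-stage MET analysis
  tolerates the resulting unbalance.
* The likelihood-ratio test between nested fits uses the plain
  chi-square reference (at df = 1 and 5% the familiar 1.92
  log-likelihood increment); the boundary-corrected half-half mixture is
  available as an option. Confidence intervals follow the standard
  forms: Satterthwaite chi-square for variance components (effective df
  `2 (estimate/se)^2`, standard errors from the numerically inverted
  observed information on the natural scale) and delta-method normal
  intervals truncated to [-1, 1] for between-season genetic
  correlations.

## Selection comparison

Rankings from different predictors (clone-only `u_c'`, nested clone
`u_c`, total genotypic `u_g`) are compared by the Czekanowski
coincidence of the top 20% selections, CC = a/(a + b), and the
tie-aware Spearman rank correlation. For MET data the FAI-BLUP index
summarises all trait-by-season BLUPs: loadings are extracted by
principal components of the correlation matrix of the BLUP table,
rotated by varimax; factor scores use weighted least squares (Bartlett);
ideotypes are placed at the desirable pole of every variable (observed
maxima for higher-is-better traits) and projected into score space, and
genotypes are ranked by normalised inverse Euclidean distance to the
all-desirable ideotype, P_ij = (1/d_ij) / sum_i (1/d_ij). Distances are
floored at 1e-12 before inversion. Because Bartlett scores transform
orthogonally under rotation, the final index does not depend on the
rotation details — a property the test suite exploits with an unrotated
oracle. The number of factors defaults to the eigenvalue >= 1 rule and
can be fixed (e.g. 3 factors for 6 season-by-trait variables). Both
tuber yield and specific gravity are treated as higher-is-better (higher
specific gravity means more dry matter).

Open design points we resolved: ideotypes could be built per factor-pole
combination (2^k variants); the full set is computed, but the ranking
target is the all-desirable ideotype. When two traits are analysed, each
season-by-trait BLUP column enters the index as its own variable.

## The synthetic trial generator

The field data behind the original study are not deposited, so the
package ships a generator that reproduces the designs and the
statistical structure the models assume, plus truth records for
parameter-recovery testing:

* `abd_design()` divides clones evenly across blocks (remainder to the
  first blocks, after a seeded shuffle) and replicates every check once
  per block; `prep_design()` duplicates `d = round(p_N N_treat / (1 -
  p_N))` entries, sampled uniformly under the seed, never twice in the
  same block. Layout invariants and the published `p_N` values (e.g.
  22.71% for a 48-block, 477-clone, 3-check ABD) are reproduced exactly.
* `simulate_phenotypes()` draws family and clone effect vectors across
  trials from multivariate normals with covariances `G_ts` and `G_tc`,
  blocks and residuals independently per trial, and fixed means for
  check plots (checks are fixed effects, so they receive no genetic
  draw). Traits are simulated independently — the models analyse traits
  separately, and cross-trait genetic correlation would only matter for
  the index stage. A uniform missingness rate is available (default 0).

The packaged scenario (`default_sim_params()`) mirrors the study
conditions: three seasons without/moderate/high heat stress, 30 families
of 15 clones, three checks, and two traits. Total tuber yield declines
from 30 to 17.4 Mg/ha under high stress (a ~42% drop), its family
variance halves twice across the stress gradient (5.7, 3.7, 1.8) while
the clone variance grows, and its between-season genetic correlations
are 0.4 (complex interaction); specific gravity sits near 1.08 with
variance components around 1e-5, family share ~30% of the genetic
variance and correlations 0.7 (simple interaction). Block and residual
variances are heterogeneous per season at fractions comparable to the
published percent-contribution tables. Per-family clone counts are
equal by default since only family totals are published.

What the generator does not emulate: spatial row-column trends within
blocks, weather-driven covariates, multi-year seed-lot carryover, or
non-Gaussian trait distributions. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated model, not
robustness to field artefacts outside it.

## Problem sizes and runtime

The test suite fits the study-scale scenario (450 clones, 3 seasons,
P-REP with 20 blocks, ~1700 plots per trait) in a few seconds per MET
fit; parameter recovery uses 50 replicate simulations and the coverage
checks 500 replicate one-way fits, sizes chosen to keep Monte-Carlo
error well inside the tolerances they assert.

## Limitations

* No pedigree or genomic relationship matrices: relatedness enters only
  through the family/clone nesting.
* Unstructured G x E matrices are practical for a handful of trials;
  factor-analytic covariance structures for many environments are out
  of scope.
* The chi-square/normal interval procedures are asymptotic; with very
  few families the family-variance interval can undercover.
* ST models require exactly one trial and MET models at least two
  sharing the clone catalog; clones observed in a single season still
  receive MET BLUPs through the estimated between-season covariances.
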