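---
title: "Models and methods for multi-environment trial analysis of cassava processed-product traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgxe)
```

## Scope

`metgxe` analyses multi-environment variety trials (METs) of cassava
processed-product traits: the conversion rates of fresh roots into gari and
dried fufu (product weight as a percentage of the fresh-root weight loaded
into processing), the associated processing losses (peel, insoluble fiber),
and fresh/dry root yield. The pipeline runs from plot-level records to
selection decisions: trait derivation, REML variance components and
heritability, deregressed BLUPs and their cross-trait correlations, a
genotype × environment table of adjusted means, three
genotype-by-environment interaction (GEI) models (Finlay–Wilkinson, AMMI,
GGE), and two stability indices (Wricke's ecovalence and the geometric
adaptability index). A synthetic-trial generator with a stored truth record
backs every estimator with parameter-recovery tests.

## Derived traits

Conversion rates are ratios of recorded weights:
gari% = 100 · gari weight / starting root weight, and analogously for dried
fufu, peel loss and fiber content. No correction is applied for the
starting mass (processing batches are typically 20 kg, sometimes 10 kg when
roots are scarce): the rate is a ratio of what was weighed. Fresh root
yield converts the plot root weight (kg) to t/ha through the ground area
per plant (default 0.8 m²):

$$\mathrm{FYLD} = \frac{\mathrm{RTWT}}{n_{\text{harvested}} \times 0.8}
  \times 10, \qquad
  \mathrm{DYLD} = \mathrm{FYLD}\times \mathrm{DM}/100 .$$

The denominator uses the count of plants actually harvested, not the
nominal 20-plant net plot: with missing plants a fixed divisor would
deflate yield for reasons unrelated to the genotype. Derivations with any
missing parent produce missing values, never errors, and missingness is
carried explicitly (a single `NA` sentinel) into every downstream stage.

## The overall mixed model

For each trait the across-environment analysis fits, by REML,

$$y = X\beta + Z_g u_g + Z_E u_E + Z_{r(E)} u_{r(E)} + Z_{gE} u_{gE} + e,$$

with independent random effects for genotype, environment, replication
nested in environment, and genotype × environment, each
$u_k \sim N(0, \sigma_k^2 I)$, and $e \sim N(0,\sigma^2_\varepsilon I)$.
Genotypes carry an identity covariance (no pedigree or genomic
relationships). The fixed part holds the intercept and linear row/column
spatial trends. Trial sets differ between environments, so the trends are
nested within set × environment; coding them as centred covariates (rather
than per-position factors) matches the linear spatial trends the generator
produces and keeps the fixed design small and full-rank.

### Estimation

The engine works on the mixed-model equations with
$\lambda_k = \sigma^2_k/\sigma^2_\varepsilon$,
$C = W'W + \mathrm{diag}(0_p, \lambda_k^{-1} I_{q_k})$, $W = [X\;Z]$:

$$-2\ell_R = (n-p)\log(2\pi\sigma^2_\varepsilon)
  + \sum_k q_k \log\lambda_k + \log|C|
  + (y'y - \hat s' W'y)/\sigma^2_\varepsilon ,$$

where $C\hat s = W'y$. The residual variance is profiled out analytically.
Maximisation proceeds in two phases: a short EM warm-up (default 8
iterations) whose updates are boundary-safe and monotone in the restricted
likelihood, then a bounded quasi-Newton (L-BFGS-B) polish of the profiled
criterion in the variance ratios. The EM phase needs the diagonal of
$C^{-1}$ and is skipped automatically when $\dim(C) > 1500$; the
quasi-Newton phase needs only sparse Cholesky factorisations (via the
Matrix package) and scales to the ~4500-dimensional systems of the
500-genotype validation runs in a few seconds. Convergence is declared at
a relative tolerance of 1e-8 (cap 500 iterations).

Variance components are constrained non-negative by the box bound; a
component whose ratio collapses to the boundary is reported as an explicit
"pinned at 0" state rather than a tiny positive number, mirroring how
insignificant replication terms are usually reported. Standard errors come
from a central-difference Hessian of the unprofiled restricted
log-likelihood at the optimum ($\widehat{\mathrm{Var}} = 2H^{-1}$ for the
$-2\ell_R$ Hessian); z-tests are one-sided, the natural choice for
boundary-constrained variances. Percent variance explained divides each
component by the sum of all components including the residual.

BLUPs, their prediction-error variances (PEV), and the genotype block of
$C^{-1}$ come from the converged equations. The engine reproduces lme4 on
the same data to the printed precision of both (this is asserted in the
test suite), and reduces exactly to the ANOVA method-of-moments components
on balanced data.

### Heritability

Two broad-sense estimators on an entry-mean basis:

$$H^2_{\text{standard}} =
  \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gE}/e + \sigma^2_\varepsilon/(er)},
\qquad
H^2_{\text{Cullis}} = 1 - \frac{\bar v_{\Delta}}{2\sigma^2_g},$$

with $e$ environments and $r$ replicates. $\bar v_\Delta$ is computed
exactly as the mean over all genotype pairs of
$\mathrm{Var}(\hat u_i - \hat u_j) = \mathrm{PEV}_i + \mathrm{PEV}_j -
2\,\mathrm{Cov}_{ij}$ from the genotype block of the inverse coefficient
matrix; the common approximation $2\,\overline{\mathrm{PEV}}$, which drops
the covariances, is available as an option (`method = "mean_pev"`) because
"average standard error of the BLUPs" is often reported that way. On the
balanced designs the generator produces, the two heritability estimators
agree to about 0.01.

Per-trial heritability refits the single-trial model (genotype and
replication random, row/column trends fixed) within each environment and
reports the Cullis value. Inside one trial the genotypic and GEI variances
are confounded — no single-environment estimator can separate them — so
the per-trial value targets
$(\sigma^2_g+\sigma^2_{gE})/(\sigma^2_g+\sigma^2_{gE}+\sigma^2_\varepsilon/r)$,
and averages of per-trial heritabilities should be read accordingly.

### Deregression

Downstream correlation analysis uses deregressed BLUPs,
$\mathrm{DRBLUP} = \mathrm{BLUP}/w$ with reliability
$w = 1 - \mathrm{PEV}/\sigma^2_g$, which removes shrinkage: the regression
of DRBLUPs on true genetic values has unit slope (the BLUP-on-truth slope
is the mean reliability). Genotypes at or below a reliability floor
(default 0.1) get a missing DRBLUP — dividing by a near-zero reliability
only amplifies noise. Deregression does **not** de-attenuate Pearson
correlations between traits: the correlation of two traits' DRBLUPs
converges to $r_g\sqrt{w_a w_b}$, so with mean reliabilities around 0.8 a
true genetic correlation of 0.8 is observed near 0.67. This attenuation is
a property of any unweighted correlation of noisy genotype estimates and
is worth remembering when reading trait-correlation matrices.

## The genotype × environment table

GEI and stability models consume a complete genotype × environment matrix
of adjusted means (BLUEs). These are computed per environment — genotype
fixed, replication random, spatial trends fixed — because a joint fit with
genotype fixed yields only main-effect estimates, not the cell table the
GEI models need; per-environment adjusted means are the convention of the
MET packages this design follows. Missing cells (genotype absent from an
environment) are imputed by an EM scheme: iterate the additive row+column
fit to convergence, then refine with a rank-1 SVD term of the residual,
both to a 1e-8 tolerance. Tables with more than 20% missing cells (or an
entirely missing row/column) are rejected rather than imputed.

Before the Finlay–Wilkinson fit the table is standardised to overall mean
0, SD 1, so sensitivity slopes and mean-square deviations are comparable
across traits with different units. Wricke's ecovalence and the geometric
adaptability index always operate on the **unscaled** table: a geometric
mean of mean-centred values is meaningless, and ecovalence in original
units keeps its identity with the interaction sum of squares visible.

## GEI models

All three models partition the same corrected total SS of the table, and
several exact identities tie them together (each is asserted numerically
in the tests at 1e-8 relative tolerance):

* **Finlay–Wilkinson** regresses each genotype's row on the environmental
  index (column mean − grand mean); the two-step estimator is exact for a
  complete, equally weighted table. Slopes are reported so that the
  average genotype has sensitivity 1 and the unweighted slope mean is
  exactly 1. Sensitivity-heterogeneity SS + deviation SS = interaction SS.
* **AMMI** double-centres the table and decomposes the interaction by SVD;
  $\sum_k \lambda_k^2$ = interaction SS, and IPCA significance uses Gollob
  degrees of freedom $(n_g-1)+(n_e-1)-(2k-1)$, reported as approximate.
* **GGE** centres columns only, so the genotype main effect stays inside
  the decomposition: G+GE SS = AMMI genotype SS + interaction SS.

Scores and biplot coordinates use symmetric scaling
($u\sqrt\lambda$, $v\sqrt\lambda$) for both AMMI and GGE, fixed so
coordinates reproduce bit-for-bit across runs. Equal singular values are
flagged with a rotation-indeterminacy warning; ranking ties anywhere break
by genotype label. The which-won-where reading of the GGE biplot (the
winner of each environment sits on the PC1–PC2 polygon hull) is exact when
G+GE is rank ≤ 2 and degrades as higher axes carry structure: with
realistic noise shares (PC1+PC2 around 60% of G+GE) a substantial fraction
of winners sits off the 2D hull, so `gge_winners()` reports hull
membership against the brute-force per-environment argmax rather than
assuming the vertex rule.

## Stability indices and selection

Wricke's ecovalence $W_i = \sum_j (x_{ij}-\bar x_{i\cdot}-\bar
x_{\cdot j}+\bar x_{\cdot\cdot})^2$ is each genotype's contribution to the
interaction SS ($\sum_i W_i$ = interaction SS exactly, and $W_i$ equals
the squared norm of the genotype's full-rank AMMI interaction loadings);
low values mean static stability. The geometric adaptability index
$\mathrm{GAI}_i = (\prod_j x_{ij})^{1/E}$ (computed in log space; defined
only for all-positive rows) rewards consistently high performance and
never exceeds the arithmetic row mean. The selection rule intersects the
top-k of either index with genotypes above the population mean —
candidates must be both superior and stable — and reports the overlap of
the two indices' top-k sets, which is typically small since the indices
measure different things.

## The synthetic-trial generator

`simulate_met()` emulates the design of the study the package is built
around: 67 genotypes (62 advanced lines split over two overlapping trial
sets plus 5 checks shared by both), 8 location-year environments, 2
replications, and a 6×6 plot grid per set and replicate with recorded
row/column coordinates. Phenotypes follow

$$y = \mu + g_i + E_j + (b_i - 1)E_j + ge_{ij} + r_{k(j)}
  + s^{row}(row - \overline{row}) + s^{col}(col - \overline{col})
  + \varepsilon,$$

with genetic values drawn jointly across traits from a specified genetic
correlation matrix (mildly non-PSD inputs are repaired by eigenvalue
clipping; larger violations are rejected). The sensitivity slope enters as
$(b_i-1)E_j$ on top of the additive model, so the marginal regression of a
genotype on the environment mean has expected slope $b_i$ while
$\sigma^2_{gE}$ keeps its meaning as residual (non-regression)
interaction. The alpha-lattice incomplete blocks of a real trial are
approximated by linear row/column trends per set × environment — the
analysis models fit rows and columns, not blocks, so this is the structure
the estimators can actually see. All randomness flows from one master seed
through named sub-streams, so adding a trait or stage never shifts
another's draws and every run is exactly reproducible.

Default parameter choices, made once:

* `cassava_uyt_traits()` encodes the study-like preset: conversion-rate
  means near 19–20%, dry matter near 37%, fresh yield near 33 t/ha; genetic
  correlations 0.80–0.84 among dry matter and the conversion rates and
  near zero with fresh yield; variance shares that put entry-mean
  heritability near 0.7 for the conversion rates with environment the
  largest single component; slope spreads of 0.2 (gari%) and 0.4 (fufu%)
  matching the reported slope variances (0.04, 0.16); 5% missing plots.
* The generic `trait_spec()` default uses `env_effect_sd = 4` (environment
  dominating, as in most METs). This default also makes slope recovery
  informative: with only 8 environments the Finlay–Wilkinson slope is
  estimated against the spread of the environmental index, and a weak
  index (SD ≲ 2) leaves slope estimates mostly noise regardless of the
  estimator.
* Within-trial spatial trend magnitudes are not reported for the study;
  the defaults (0.05–0.2 trait units per plot position) are assumptions
  and are configurable.

What the generator does **not** emulate: genomic/marker structure (
genotypes are labels with latent values), non-normal residuals, outlier
plots, spatially autocorrelated error beyond linear trends, and
environment-specific error variances. Passing recovery tests therefore
demonstrates correctness of the estimators under the assumed model, not
robustness to every pathology of field data.

## Problem sizes and numerical choices

The validation experiments use the study dimensions (67 × 8 × 2; ~1100
plots; mixed-model equations of dimension ~630) for the 100-replicate
variance-component recovery, and 505 genotypes (~8000 plots, MME dimension
~4500) for the deregression and genetic-correlation experiments, sizes at
which the full set runs in a few minutes on one core. Other numerical
choices: imputation and REML tolerances 1e-8; variance ratios bounded in
[1e-10, 1e8] with pinning below 1e-6; zero-variance tables refuse to
scale; a starting weight of zero with a positive product weight is a data
error (a physical impossibility), while a zero harvested-plant count
yields a missing yield.

## Limitations

Single-trait REML only (multi-trait genetic correlations are estimated
from DRBLUPs, with the attenuation noted above); identity genotype
covariance; no mega-environment delineation or biplot graphics beyond
coordinates, cosines and hull flags; Gollob F-tests for IPCA significance
are known to be liberal; and the per-environment BLUE step assumes enough
replication within each trial to separate genotype from plot noise — a
single-replicate environment falls back to ordinary least squares.
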