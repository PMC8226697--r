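---
title: "Random regression test-day models for somatic cell score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression test-day models for somatic cell score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtdm)
```

## The model

`rrtdm` estimates genetic parameters for dairy test-day traits — somatic
cell score (SCS) and production traits — with a multiple-trait random
regression animal model. A record of trait value $y$ on cow $l$ at days in
milk (DIM) $t$, in herd-test-day class $i$ and age-season class $j$, is
modelled as

$$
y = \mathrm{HTD}_i
  + \sum_{b=0}^{4} \mathrm{AS}_{jb}\,\phi_b(t)
  + \sum_{b=0}^{2} a_{lb}\,\phi_b(t)
  + \sum_{b=0}^{2} \mathrm{pe}_{lb}\,\phi_b(t)
  + e,
$$

where $\phi_b$ are normalized Legendre polynomials evaluated at the
standardized DIM, $\mathrm{HTD}_i$ is a fixed herd-test-day class effect
nested within parity (all cows of a herd measured on the same day in the
same parity), $\mathrm{AS}_{jb}$ are fixed age-season-of-calving regression
coefficients of order 4, $a_l$ and $\mathrm{pe}_l$ are random additive
genetic and permanent environmental regression coefficient vectors of order
2, and $e$ is a residual. The overall mean is absorbed into the HTD
classes: a separate mean equation would be confounded with them, and the
absorption is invisible in the variance components.

Distributional assumptions: $\mathbf{a} \sim N(0, A \otimes K_a)$ over all
pedigree animals, with $A$ the numerator relationship matrix;
$\mathbf{pe}_l \sim N(0, K_{pe})$ independently per cow;
residual vectors of the traits recorded on the same test-day are
$N(0, R)$, independent across test-days and homogeneous across DIM.
Residuals of different parities are independent (two parities are never
measured on the same cow-day). When parities are analysed as separate model
traits, the permanent environment vector is defined per cow per model
trait, so it is effectively within-parity.

The quantities of interest are covariance *functions*: the additive genetic
covariance between DIM $t$ and $s$ is $\phi(t)' K_a \phi(s)$, and likewise
for the permanent environment. Daily heritability is

$$
h^2(t) = \frac{\sigma^2_a(t)}
              {\sigma^2_a(t) + \sigma^2_{pe}(t) + \sigma^2_e},
$$

and daily between-trait genetic correlations are
$r_a(t) = \mathrm{cov}_a(t) / \sqrt{\sigma^2_{a,1}(t)\,\sigma^2_{a,2}(t)}$,
with analogous permanent environmental and phenotypic versions (the
phenotypic cross-covariance adds the residual covariance for trait pairs
recorded on the same day).

## Legendre basis and standardization

DIM is standardized linearly from the edit window $[5, 365]$ onto
$[-1, 1]$; the same window is used for all parities. The basis is the
*orthonormal* Legendre family
$\phi_b(x) = \sqrt{(2b+1)/2}\, P_b(x)$, the convention dominant in random
regression test-day software; the classical unnormalized $P_b$ is available
behind a flag (`legendre_basis(..., normalized = FALSE)`) because the
choice only rescales the coefficient covariance matrices, not the fitted
covariance functions. Orthonormality gives the convenient identity that the
average of $\phi_b(t)^2$ over a uniformly distributed standardized DIM is
$1/2$ for every $b$, so the DIM-average genetic variance of a trait is
$\mathrm{tr}(K_a)/2$; the package's tests use this identity as an oracle.

## Data edits

`apply_edits()` applies the standard edits in a fixed, documented order
(parse validity, parity cap, trait completeness, DIM window, age at first
calving, lactation nesting), because the per-rule removal counts depend on
the order. Conventions worth stating:

* both windows are inclusive — DIM 5 and 365 are kept, ages at first
  calving of exactly 640 and 1200 days are kept;
* a test-day missing any required trait is removed entirely (the sampler
  never imputes residuals);
* a somatic cell count of zero or below cannot be transformed
  ($\log_2$ is undefined) and is treated as a missing trait;
* the age-at-first-calving rule removes the whole cow, not single records,
  since the age is a cow-level quantity; a cow whose first lactation is
  absent has no computable age and is removed by the same rule;
* the lactation-nesting rule keeps a parity-$k$ lactation only when
  parities $1..k-1$ are present for that cow;
* age-season classes combine the calving season (winter = January–March
  and so on) with five within-parity age-at-calving bins. The five
  cutpoints are rarely published, so the default uses within-parity
  quintiles of the observed ages, which balances class sizes; explicit
  cutpoints can be supplied. An age exactly at a cutpoint falls in the
  lower bin; ages outside the cutpoint range are clamped to the edge bins
  with a warning.

## Pedigree machinery

Pedigrees are topologically sorted with cycle detection; parents appearing
only as parents are appended as founders, as are phenotyped cows missing
from the pedigree (with a warning). Inbreeding coefficients use the
Meuwissen–Luo recursion, and the sparse inverse of the numerator
relationship matrix is built directly by Henderson's rules with
Mendelian-sampling variances $d_i = 1/2 - (F_s + F_d)/4$. Inbreeding is
accounted for by default — deep dairy pedigrees make $F > 0$ common, and
the widely used samplers default to it — with `use_inbreeding = FALSE`
available for textbook comparisons. Unknown parents are one phantom,
non-inbred, unrelated base population; unknown-parent groups are out of
scope. A dense tabular-method `a_matrix_dense()` exists purely as a test
oracle and refuses large pedigrees.

## Gibbs sampler

Variance components are estimated by Bayesian inference with a single-chain
Gibbs sampler written in compiled code.

**Location effects** are drawn in blocks from their multivariate normal
full conditionals: one vector per herd-test-day class, one order-4
coefficient vector per age-season class and trait, and — the important
design choice — one *joint* draw of the additive and permanent
environmental coefficient pair of each phenotyped cow (a $2q$-dimensional
block per model trait set). The likelihood sees only the sum of a cow's two
effects, so updating them separately leaves their difference on a slow
random walk; the joint draw removes that walk. Animals without records get
their additive vector from the pedigree prior conditional on relatives.

**Covariance components** have inverted-Wishart full conditionals:
$K_a \mid \cdot \sim \mathrm{IW}(\Psi_a + U' A^{-1} U,\ \nu_a + n)$ with
$U$ the matrix of additive coefficient vectors, and analogous identity-
weighted forms for $K_{pe}$ and $R$.

**Scaled reallocation moves.** Even with joint cow blocks, the *scale*
split between $K_a$ and $K_{pe}$ mixes slowly: a chain that wanders into a
small-$K_a$ state shrinks the additive effects, which in turn keeps $K_a$
small. The sampler therefore adds, each iteration, a pair of generalized
Gibbs moves per trait block along likelihood-invariant group orbits:

* scale the additive block, $u \to \alpha u$ and
  $K_a \to D K_a D$ ($D$ diagonal with $\alpha$ on the block), while
  shearing the permanent environment, $p \to p + (1-\alpha) u$, so every
  fitted value is unchanged;
* the mirror move scaling the permanent environmental block and $K_{pe}$.

$\log \alpha$ is slice-sampled from its exact induced density (the prior
quadratic forms, the inverted-Wishart terms and the transformation
Jacobians), so the moves leave the posterior invariant — a property the
test suite checks by comparing marginal posterior quantiles against a much
longer chain run without the moves — while letting the additive/permanent
environment split equilibrate in a few iterations instead of thousands.

**Priors and starting values.** Fixed effects have flat priors. Covariance
priors are weakly informative inverted Wisharts with degrees of freedom
$\dim + 2$ and scale equal to the starting matrix, so the prior mean equals
the start. Starting values use a phenotypic-variance split: coefficient
diagonals sized so the DIM-average additive and permanent environmental
variances are each 20% of the observed phenotypic variance, and the
residual 60%. All of this is configurable through `default_priors()`.

**Chain settings.** The defaults follow common practice for this model
class: a single chain, burn-in discarded, every 10th post-burn-in sample
stored (thinning is storage pragmatism; estimators use all stored samples).
Convergence is reported quantitatively — effective sample size by Geyer's
initial positive sequence and the Geweke first-10%-vs-last-50% z score —
rather than by visual inspection of trace plots. A divergence guard aborts
if the covariance traces exceed $10^6$ times their starting values.
Near-singular conditional precisions receive a relative jitter of
$10^{-10}$, standard mixed-model practice.

## The synthetic herd generator

Because national test-day datasets are not redistributable, the package
ships a generator that draws data from exactly the model above with known
truth, so every stage is testable by parameter recovery.

* **Pedigree**: discrete generations from a founder population; every
  female of the previous generation produces a fixed number of offspring,
  with sires drawn from a limited pool of 25 active males per generation.
  Heavy sire use mirrors dairy AI breeding, and the resulting large
  paternal half-sib families carry most of the information that separates
  additive from permanent environmental variance.
* **Calendar**: each herd has a shared monthly visit calendar (herd-test-
  day is then a genuine contemporary group). A cow's first visit falls at a
  DIM uniform on $[5, 35]$; twelve monthly visits then span the full DIM
  window to 365. Calendars with fewer visits leave the late lactation
  unobserved, which inflates the extrapolated genetic variance there — the
  12-visit default avoids judging the estimator on extrapolation.
* **Effects**: additive coefficient vectors are gene-dropped down the
  pedigree (founders iid $N(0, K_a)$, offspring get the parent average
  plus a Mendelian deviation with variance $d_i K_a$, which respects
  inbreeding); permanent environment vectors are iid; herd-test-day
  effects are iid normal with configurable SD (the fit still treats them
  as fixed classes); age-season classes follow the calving season with
  smooth order-4 curves; residuals are iid multivariate normal per
  test-day.
* **Reference conditions**: the single-trait SCS-like condition uses
  $K_a = \mathrm{diag}(1.48, 0.02, 0.01)$,
  $K_{pe} = \mathrm{diag}(1.86, 0.04, 0.02)$, $\sigma^2_e = 2.44$, which
  implies a DIM-average heritability of about 0.18 — a realistic value for
  SCS. The two-trait condition uses proportional genetic blocks
  $K_a = T_0 \otimes K_1$ with $T_0 = \begin{pmatrix}1 & -0.42\\ -0.42 &
  4\end{pmatrix}$, so the true genetic correlation is exactly $-0.21$ at
  every DIM, with uncorrelated permanent environmental and residual
  blocks.

The generator deliberately omits selection and culling, heterogeneous
residual variance, missing-trait patterns within a test-day, and
genotypes. Passing recovery tests therefore shows that the estimation
machinery is correct *under the model's own assumptions* — it does not
validate the model against the ways real herds violate those assumptions
(selection bias, residual heterogeneity, preferential treatment).

## Problem sizes and what recovery can resolve

The recovery studies use desk-scale problems: 500 phenotyped cows
(pedigree of about 1,360 animals) with 20,000 iterates / 5,000 burn-in for
the single-trait condition, and 400 cows with both traits recorded for the
two-trait condition. At these sizes the DIM-average heritability is
recovered within about $\pm 0.01$–$0.02$ of truth across generator seeds.

The DIM-average *genetic correlation* is a much harder target at desk
scale. Three error sources stack: the realized correlation of a finite
founder population scatters around the generating value (about $\pm 0.06$
at 280 founders), the posterior itself is wide when 400 cows in 70-odd
sire families must separate a genetic covariance from a permanent
environmental one, and the chain's effective sample size at 20,000
iterates leaves visible Monte Carlo error. Single runs can miss the
generating value by 0.1 or more in either direction without indicating any
defect in the estimator; the posterior-invariance and oracle tests pin the
correctness down instead. This is the expected behaviour of the model
class: published analyses of this kind use millions of records and
hundreds of thousands of iterates.

## Post-processing conventions

* Heritabilities and correlations are computed *per retained sample* and
  then averaged — the posterior mean of the ratio, not the ratio of
  posterior means — with 95% equal-tailed credible bounds from the same
  per-sample values. Per-sample values are automatically valid
  ($h^2 \in [0,1]$, correlations in $[-1,1]$) because every stored sample
  is positive definite.
* Means over DIM use the unweighted integer grid of the DIM window.
* Summary tables report "mean (min to max)" over the DIM grid, the
  conventional lactation-average presentation.
* The residual homogeneity diagnostic bins observed-minus-fitted residuals
  by DIM (30-day bins by default, bins with fewer than 5 records flagged
  out) and reports the max/min SD ratio; under homogeneity with a few
  hundred records per bin the ratio stays below about 1.3, while a
  variance step of factor 2 pushes it past $\sqrt 2$.

## Known limitations

* Heterogeneous residual variance across DIM is diagnosed but not
  modelled.
* Maternal effects, dominance, genomic relationships and unknown-parent
  groups are out of scope.
* The exact grouping of traits into multi-trait runs is an analysis
  choice; the engine accepts any set of trait columns as model traits and
  treats parities as separate traits when the records are pre-split.
* Fixed-effect levels (herd-test-day and age-season) are jointly
  confounded with the absorbed mean; their individual values are not
  identified, only their data-facing sums, which is harmless for variance
  components but means reported fixed-effect solutions should be read as
  contrasts.
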