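---
title: "Quantitative genetics of biosynthesized cyanogenic toxicity: models and methods"
author: "cyanoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of biosynthesized cyanogenic toxicity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoquant)
```

## The scientific problem

*Heliconius erato* is an aposematic, mimetic butterfly that biosynthesizes
two cyanogenic glucosides — linamarin and lotaustralin — de novo. The
concentration of these compounds (expressed as % of body dry mass) is the
chemical-defense trait this package analyses. Two questions drive the
analysis: how much of the variation in toxicity is genetically determined
and therefore available to selection, and how much is shaped by ecology
(larval diet, rainfall, altitude)?

The package implements the full analysis chain as reusable functions: a
synthetic-data generator for the common-garden breeding design and the
field surveys, pedigree handling and the additive relationship matrix, REML
"animal models", derived quantitative-genetic metrics (heritability,
evolvability, repeatability, maternal effects, selection-response
projections), and the population-comparison statistics for wild samples.
The numbered scripts under `analysis/` run the chain end to end on
generated data.

## The animal model

The central model is a Gaussian mixed model in which each individual $i$
carries a genetic effect $a_i$ whose covariance structure is the additive
(numerator) relationship matrix $A$ built from the pedigree:

$$ y = X\beta + a + m + e, \qquad
   a \sim N(0, V_G A), \quad m \sim N(0, V_{mat} Z Z'), \quad
   e \sim N(0, V_R I). $$

Fixed effects $X\beta$ are sex and larval feeding treatment. "Model 1"
contains only the genetic random effect; "Model 2" adds a maternal-identity
random effect $m$ (one level per dam). $A$ is built by the standard tabular
method ($A_{ii} = 1 + \tfrac12 A_{dam,sire}$,
$A_{ij} = \tfrac12(A_{j,dam_i} + A_{j,sire_i})$), with founders assumed
unrelated and non-inbred. Broods whose sire was never observed get a
distinct phantom founder sire each (single mating per female), so their
members remain full sibs rather than maternal half sibs.

Estimation is restricted maximum likelihood. The implementation profiles
the residual variance out of the criterion and searches over log variance
ratios: Brent's method on the single ratio for one random effect (after an
eigen-rotation of $Z A Z'$ that makes each criterion evaluation $O(np^2)$),
Nelder-Mead with multiple starts for two or more. The reported criterion
includes the $-\log|X'X|$ correction, so its value is invariant to
reparameterization of the fixed effects. Convergence is assessed on
relative criterion change ($10^{-12}$ in the optimizer); variance ratios
below $10^{-8}$ are projected to the zero boundary. Standard errors come
from the observed information matrix, obtained by central finite
differences of the restricted log-likelihood (one-sided at the zero
boundary). With all phenotypes identical the fit is flagged degenerate and
every component is zero.

Two conventions are exposed for the phenotypic variance. The components
table reports $V_P = V_G + V_{mat} + V_{sex} + V_{trm} + V_R$, where
$V_{sex}$ and $V_{trm}$ are the population variances of the fixed-effect
linear predictor contributions. `broad_sense_heritability()` by default
*excludes* $V_{trm}$ from the denominator — experimentally imposed diet
variance does not represent natural variation — and offers the full-sum
denominator as an option. Because most information about $V_G$ comes from
full-sib resemblance, the estimate is a broad-sense genetic variance;
parent-offspring and paternal half-sib links in the design pull it towards
the narrow-sense value.

Testing a variance component against zero places the null on the boundary
of the parameter space, so the likelihood-ratio statistic is referred to a
50:50 mixture of a point mass at zero and $\chi^2_1$:
$p = \tfrac12 P(\chi^2_1 \ge 2\Delta\ell)$, which gives $p = 0.5$ at zero
improvement.

## Derived metrics

* **Evolvability** $e_\mu = 100\, V_G/\mu^2$: the expected percent change
  in the trait mean per generation under unit-strength selection
  (selection as strong as selection on fitness). Unlike $H^2$ it is
  unaffected by the residual variance.
* **Repeatability** $R = V_{brood}/(V_{brood}+V_{res})$ from a one-way
  random-intercept model over broods. Uncertainty comes from a parametric
  bootstrap (default 1,000 resimulations from the fitted model, each
  refitted; percentile CI), the p-value from the boundary-mixture LRT.
* **Parent-offspring regressions** are mixed models with a family random
  intercept and the parent's phenotype (constant within family) as the
  covariate. Because the covariate is group-constant, the restricted
  likelihood factorizes exactly into within-family contrasts and a
  weighted regression of family means; the package exploits this
  factorization, reducing each fit to a one-dimensional profile search.
  That is what makes $10^5$-refit bootstrap loops affordable. The same
  estimates are recovered (to numerical precision) by `lme4::lmer`, which
  the test suite uses as an independent cross-check. Slope inference uses
  $t = \hat\beta/SE$ with residual-based degrees of freedom $n - 2$.
* **Maternal-effect coefficient** $m = \beta_{mo} - \beta_{fo}$, the
  difference between the mother-offspring and father-offspring slopes
  (Falconer's dilution model: the mother's phenotype acts directly and
  linearly on the offspring phenotype beyond transmitted genes). The CI is
  a brood-level cluster bootstrap (default 1,000 draws, percentile): broods
  are resampled with replacement and both regressions refitted jointly, so
  the dependence between slopes survives resampling. The two slopes rest
  on different subsets — all broods have a phenotyped mother, only broods
  with a known sire enter the father regression — and the report surfaces
  both family counts. Under purely additive inheritance both slopes
  approach $h^2/2$ and $m \to 0$; under pure phenotypic transmission
  $\beta_{mo} \to m$ and $\beta_{fo} \to 0$.
* **Selection-response projection.** Per-generation proportional change
  $e_\mu \beta$ compounds multiplicatively:
  $100((1 + e_\mu\beta/100)^g - 1)$; six generations approximate one year
  for these tropical butterflies. With maternal transmission the
  per-generation response follows the recursion $R_t = h^2 S + m R_{t-1}$
  (the minimal phenotype-transmission form; alternative recursions with
  maternal-additive covariance terms can be plugged in through the
  `recursion` argument). Its cumulative response exceeds the breeder's
  equation by a factor approaching $1/(1-m)$ — about a 33% excess at
  $m = 0.25$. Published treatments of maternal-effect dynamics quote
  excesses up to ~50% at comparable $m$; those arise from recursions with
  additional covariance terms, which is why the recursion is pluggable
  rather than hard-coded.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every estimator is validated. Defaults reproduce the common-garden
study design: 20 full-sib broods — 14 smaller ones (8 offspring each, 8 of
the 14 with a known sire, the rest receiving phantom founder sires) and 6
large feeding-treatment broods (29 offspring each, eggs split equally
across four host-plant types) — plus their parents, one paternal half-sib
brood pair, about 322 pedigreed individuals in all. Phenotypes follow

$$ y_i = \mu + \text{sex}_i + \text{trt}_i + a_i + m_i + e_i $$

with $\mu = 0.772$, $V_A = 0.0093$, $V_R = 0.071$ (so $V_P \approx 0.080$),
a male shift of 0.059 and treatment shifts $(\pm 0.015, \pm 0.045)$ — each
calibrated so the simulated variance ratios match the reported
decomposition ($V_{sex}/V_P \approx V_{trm}/V_P \approx 0.011$). Breeding
values are drawn jointly from $N(0, V_A A)$ via the Cholesky factor of
$A$. The maternal term has two mutually exclusive modes: a dam-level
normal deviate with variance $V_{mat}$, or Falconer transmission
$m(y_{dam} - \mu)$, which requires dam phenotypes to be generated first
(founders are simulated before offspring; the generator enforces this).
Negative phenotype draws are truncated at zero — concentrations are
nonnegative; at the default parameters this affects ~0.3% of draws.
Totals are split into lotaustralin and linamarin by a per-individual Beta
fraction (mean 0.25 = the reported ratio of compound means; concentration
200, calibrated so the two compounds correlate at about $r = 0.9$ as
observed); `total = linamarin + lotaustralin` holds exactly by
construction.

Field samples are gamma (or log-normal) by mean/SD moments, optionally
with a point mass at exact zero for below-detection samples (the
Ecuadorian populations: 71% zeros). Host-plant samples are gamma by
site-level moments, optionally crossed origin × watering.

What the generator does *not* emulate: measurement error of the NMR
quantification, age structure of wild samples (a likely source of the
observed right skew), sequestered cyanogens, a parental-vs-offspring
generation shift, and any genotype-environment interaction. Passing
parameter-recovery tests therefore shows the estimators are correct under
the stated generative model, not that the model captures every feature of
the real data.

## Numerical and design choices

* Dense matrix algebra throughout: at $n \approx 350$ a full Cholesky per
  criterion evaluation costs milliseconds; sparse pedigree tricks
  (Henderson's rules, $A^{-1}$ construction) are deliberately out of
  scope.
* The kinship coefficient is implemented twice on purpose: the tabular
  matrix construction used by the models, and an independent memoized
  recursion used only as a test oracle. The suite checks
  $A = 2\,\mathrm{kinship}$ exactly on 50 random pedigrees.
* Zero-truncated weighted KDE: Gaussian kernels with the normal-reference
  bandwidth $h = 0.9\min(SD, IQR/1.34)n^{-1/5}$; each kernel is
  renormalized by its mass on $[0,\infty)$ (division by
  $\Phi(x_i/h)$), so the estimate integrates to one without reflecting
  mass across zero. Weights are normalized to sum one.
* "Lower/highest 25% of toxicity values" is read as quarters of the
  *observed range*, not quantiles (quantile quarters would hold 25% by
  construction); `range_quartile_summary` flags constant data as an error
  because the range interpretation is undefined there.
* Tukey comparisons use the Tukey-Kramer form (group sizes in the surveys
  are unequal: 34/28/30 butterflies, 20/11/20 plants) on the same
  square-root scale as the ANOVA.
* One-way and two-way ANOVAs, Tukey HSD and the Pearson test delegate to
  `stats`; Hedges' g (pooled-SD standardized difference with the
  $1 - 3/(4\,df-1)$ small-sample correction) is implemented directly.
* Random-number use is seeded everywhere a draw occurs (generator configs
  carry a seed; bootstrap functions take one), and identical seeds
  reproduce outputs byte-identically.

## Validation strategy and problem sizes

The test suite validates each estimator against an independent route:
balanced-design closed forms (ANOVA mean squares, the balanced ICC), a
dense grid search and 1,000 random probes of the restricted likelihood,
`lme4` refits, brute-force kernel sums, and exhaustive counting. Stochastic
properties run at sizes chosen to keep the full suite within minutes while
leaving Monte-Carlo error well below the tolerances tested: 100 replicates
of the 20-brood × 16-offspring design for parameter recovery (bias within
two empirical standard errors for $V_G$, $H^2$, $e_\mu$, $R$), 100
replicates of a 30-brood × 12-offspring Falconer design with 400-draw
cluster bootstraps for CI coverage (the larger brood count keeps
percentile-bootstrap coverage near its nominal level), 200 replicates for
the null size of the boundary LRT.

## Known limitations

* The REML engine targets small-to-moderate pedigrees (hundreds of
  individuals); it makes no attempt at sparse scaling.
* Variance-component SEs are asymptotic and unreliable at the zero
  boundary (reported as `NA` when the information matrix is singular).
* The father-offspring regression conditions on the sire-known subset of
  broods; with few such broods the maternal-effect difference $m$ is
  noisy, and its two slopes are not estimated on identical data — an
  inherent feature of the design, surfaced rather than hidden.
* Single-trait analyses only: no multivariate REML, no maternal-effect
  covariance matrices, no dominance or epistatic decomposition.
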