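---
title: "Methods: biometric twin models in twinkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biometric twin models in twinkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinkit)
```

## The model and its assumptions

`twinkit` implements the classical biometric decomposition for continuous
traits measured on twin pairs in five zygosity groups (MZ male, DZ male,
MZ female, DZ female, opposite-sex DZ). The trait vector of each twin is
modelled as a sum of latent component scores,

$$y = a + d + c + e,$$

where the additive genetic score $a$ correlates 1.0 across MZ cotwins and
0.5 across DZ cotwins, the non-additive (dominance/epistatic) score $d$
1.0 and 0.25, the shared-environmental score $c$ 1.0 in both, and the
individual-specific score $e$ (which absorbs measurement error) 0 in both.
C and D are never estimated jointly: with twin pairs only, they push the
MZ/DZ correlation pattern in opposite directions and are not separable, so
ACE and ADE models are fitted separately and compared by AIC.

For $T$ traits, each active component's covariance matrix is parameterized
as $\Sigma_X = L_X L_X^\top$ with $L_X$ lower-triangular (the Cholesky
parameterization), which guarantees positive semi-definiteness without
inequality constraints. The implied covariance of the stacked pair vector
is

$$\Sigma_{\text{pair}} =
\begin{pmatrix} \sum_X \Sigma_X & \sum_X \alpha_X \Sigma_X \\
                \sum_X \alpha_X \Sigma_X & \sum_X \Sigma_X \end{pmatrix},$$

with the zygosity weights $\alpha_X$ above. Estimation is raw-data
full-information maximum likelihood: each pair contributes the Gaussian
$-2\log L$ of whatever cells it has observed, so pairs with one missing
twin contribute their marginal likelihood and nothing is listwise-deleted.
Means are fixed at zero because model fitting operates on residualized,
standardized scores (a `free_means` switch estimates one mean per trait as
a sensitivity check; it deliberately does not free means per group, which
the zero-mean residual scale makes redundant).

Distributional assumptions: multivariate normality of the component scores
(hence of the residualized traits), homogeneous covariances within
zygosity group, independence across families, and random mating (no
assortment), no gene--environment correlation or interaction — the
standard assumptions of the design.

### Sex limitation

Three levels are supported. `none` shares all loadings across sex.
`common_effects` frees separate male and female loading matrices
(quantitative sex differences) while keeping the opposite-sex genetic
weight at its DZ value. `general` additionally frees the opposite-sex
genetic correlation `rg_dos`, bounded in $[0, 0.5]$ and attached to the A
component — or, when A is absent from the model, to D with bounds
$[0, 0.25]$. This "free cross-sex correlation" mechanism is one of two
conventions for qualitative sex limitation (the other being a sex-specific
genetic factor); it was chosen because it nests the no-sex-difference
model at the bound and adds exactly one parameter.

## Preprocessing

The preparation chain pools both members of every pair and, per trait:

1. computes skewness (adjusted Fisher--Pearson $G_1$, the common software
   default; the magnitude regime matches published indices of ~0.6--0.8
   for positively skewed [0,1] questionnaire scores);
2. applies a square-root transform when skewness exceeds a threshold
   (default 0.5, configurable and overridable per trait — chosen so that
   scores with skewness ≈ 0.6--0.8 transform while a near-symmetric score
   with skewness ≈ −0.1 does not);
3. residualizes on $\{1, \text{sex}, \text{age}, \text{sex} \times
   \text{age}, \text{age}^2\}$ by OLS and standardizes the residuals.

The transform precedes residualization (the natural reading of the
source workflow, which discusses transformation with the descriptives and
adjustment with the model fitting; the alternative order changes nothing
qualitatively). Twin non-independence is ignored in the OLS step: only
the mean-model point estimates are used, never their standard errors.
Standardization makes fitted variance components directly interpretable as
proportions, which is the scale on which results are reported.

## Descriptive correlation layer

`ml_twin_correlation()` estimates the within-trait twin correlation per
group under a bivariate normal with means and variances constrained equal
across twin order — the likelihood formulation that is invariant to the
arbitrary labelling of twins without double entry (which would inflate n).
For opposite-sex pairs the order is fixed male-first and moments are free
per position. `cross_twin_cross_trait()` generalizes this to a 4-variate
twin-order-symmetric model; on complete data its MLE is the
twin-order-symmetrized sample covariance, and with missing cells it is
obtained numerically. Cross-twin cross-trait tables are computed on
residualized scores, and DOS pairs are counted in the DZ class by default
(`include_dos = FALSE` restores the same-sex-only reading). Confidence
intervals are profile-likelihood based throughout (deviance increase of
$\chi^2_1(0.95) = 3.84$), with Fisher's $z$ used only as the optimizer's
internal scale.

## Numerical choices

* **Optimizer.** Bounded quasi-Newton (`nlminb`) with an analytic
  gradient of the FIML deviance (validated against central differences in
  the test suite). The likelihood decomposes over (group × missingness
  pattern) cells summarized once by count/sum/scatter, so an evaluation
  costs a handful of 2T×2T Cholesky factorizations.
* **Starts and restarts.** The first start solves the component
  covariances from pooled MZ/DZ-class cross-twin blocks (e.g.
  $\Sigma_A = 4B_{DZ} - B_{MZ}$, $\Sigma_D = 2B_{MZ} - 4B_{DZ}$ for ADE),
  projects them to PSD and takes Cholesky factors; further restarts are
  deterministic jitters of it. The default is 3 restarts, not a larger
  number: with moment-based starts and analytic gradients the fits land on
  the same optimum essentially always, and the restart count is a
  user-visible knob for harder problems. A stalled run (iteration limit on
  a flat A/D ridge) is polished by re-starting the optimizer from its own
  endpoint, which resets the Hessian approximation.
* **Tolerances.** Relative convergence tolerance 1e-10 on the deviance;
  trait-order permutation of a Cholesky fit reproduces $-2LL$, AIC,
  proportions and component correlations to 1e-4 (tested).
* **Bounds and boundaries.** Diagonal loadings are bounded at 0 (sign
  convention); the E diagonal at 1e-4 so the implied covariance stays
  positive definite. Estimates within 1e-6 of zero are reported as exact
  zeros and flagged as boundary solutions. When a component's variance for
  a trait is at the zero boundary its correlations involving that trait
  are reported as `NA` with a flag — never as 0, which would silently
  misstate pleiotropy.
* **Model comparison.** Likelihood-ratio tests use the naive $\chi^2$
  reference even when the constraint lies on a boundary, matching
  long-standing twin-modelling practice; this is conservative for
  rejecting variance components.
* **Profile intervals for derived quantities** (proportions, component
  correlations) come from constrained re-optimization: the constraint
  $g(\theta) = t$ is enforced by a two-stage quadratic penalty
  ($\lambda = 10^4$ then $10^7$) with warm starts, and the bound is
  located by root-finding on the profiled deviance. The delta method was
  rejected because these targets sit near boundaries exactly where it
  fails. On a quadratic deviance the machinery reproduces the Wald
  interval to 1e-6 (tested).

## The synthetic-data generator: the stated world

`simulate_twins()` draws each pair's stacked trait vector from the
model-implied pair covariance of a generating `param_set` and then adds
mean structure; with a fixed seed the output is bit-reproducible. The
shipped reference configurations encode the published study as the
simulation world:

* **Sample composition** 365/173/675/271/258 pairs (MZm/DZm/MZf/DZf/DOS);
  these counts are treated as *pair* counts, the unit of the twin
  likelihood. Ages are truncated-normal, mean 19.1, SD 3.1, range 11--29
  years, shared within a pair.
* **`de_reference_config()`** builds the trivariate D+E world from the
  published best-fitting values: genetic variance shares
  (0.76, 0.70, 0.47), $r_d = (-0.92, -0.55, 0.19)$ and
  $r_e = (-0.62, -0.44, -0.40)$; both implied correlation matrices are
  verified positive definite (smallest eigenvalues ≈ 0.006 and 0.04 —
  the published solution sits close to, but inside, the PSD boundary).
  Total variance per trait is exactly 1.
* **Mean effects.** The source reports sex differences as t statistics
  (7.42, −4.47, −6.32 on ~3,500 individuals) and age correlations between
  −0.09 and 0.05. Converted to the standardized trait scale these give
  male−female differences of roughly +0.25, −0.15, −0.21 SD and age slopes
  of $r/\mathrm{SD(age)}$; those are the generator defaults
  (age × sex and age² effects are zero — none are reported — but both
  terms remain in the adjustment design). These conversions were fixed
  once, before any recovery experiment was run.
* **`sexlim_reference_config()`** encodes the univariate TE regime with
  published total genetic proportions 0.71 (male) and 0.81 (female). The
  A/D split within each sex is not published; the defaults
  (male $a^2 = 0.10, d^2 = 0.61$; female $a^2 = 0.40, d^2 = 0.41$) encode
  the reported qualitative pattern — non-additive effects predominant in
  males, additive effects substantial in females — and are an explicit
  choice exposed as arguments. Only the per-sex totals are asserted by the
  recovery tests.
* **Skew emulation** (`skew_transform = "square"`): scores are mapped
  through their normal CDF and squared, landing in [0,1] with skewness
  ≈ 0.64 — inside the published 0.6--0.9 regime — so the square-root
  stage has something real to undo. The default is `none`, the Gaussian
  scale on which models are actually fitted.
* **DOS genetic weights** default to the same-sex DZ values (no
  qualitative sex differences), consistent with the source's conclusion
  that sex-specific genetic effects were not significant.

What the generator does *not* emulate: questionnaire item structure and
the compositional coupling of the scores (simulated traits are jointly
Gaussian with the published correlation structure, not sums of weighted
item responses), zygosity misclassification (~10% of questionnaire-based
diagnoses), informative missingness, and age-heterogeneous variance
components. A green recovery test therefore establishes that the
estimation machinery inverts the generative model it assumes at realistic
sample sizes — not that the published analysis was free of these
real-data complications.

## Validation design

Because the raw data are not deposited, acceptance is parameter recovery:
20 seeded replicates are simulated from `de_reference_config()` at the
published group sizes, refitted with the DE Cholesky by FIML, and the
replicate means of the six component correlations and three total-genetic
percentages are required to sit within ~2 Monte-Carlo standard errors of
the generating values; the univariate sex-limitation experiment recovers
the female total-genetic percentage the same way. On the same replicates
the model-comparison ladder must reproduce the published selection
behaviour (ADE beats ACE on AIC; dropping D covariances is rejected at
p < .05; dropping all of A is retained). Oracle-equivalence tests pin the
FIML deviance to the closed-form Gaussian expression, the Cholesky product
to brute-force summation, and the ML correlation to a grid-search
maximizer on a 50-pair fixture.

## Known limitations

* With twin pairs only, "non-additive genetic" correlations absorb any
  additive genetic overlap; at realistic sample sizes the D and A
  contributions to a cross-trait correlation are not separable, and the
  recovered $r_d$ should be read as a total-genetic correlation.
* The naive $\chi^2$ for boundary LRTs is conservative; AIC comparisons
  are unaffected.
* Profile bounds that run into a natural range limit (a correlation at
  ±1, a proportion at 0 or 1) are reported at the limit and flagged
  rather than extrapolated.
* The OLS mean model assumes mean effects are linear-quadratic in age and
  additive in sex; spline or age-band adjustments are out of scope.
* CLI configuration files are JSON (not YAML), keeping the dependency
  footprint to base R plus `jsonlite`.
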