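---
title: "Induced interaction from categorized exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Induced interaction from categorized exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spurint)
```

## The model and what "spurious" means here

Throughout, the data-generating model is linear and interaction-free:

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \varepsilon, \qquad
(X_1, X_2) \sim N(0, \Sigma), \quad
\Sigma = \begin{pmatrix} 1 & \rho \\ \rho & 1 \end{pmatrix},$$

with $\varepsilon \sim N(0, \sigma^2)$ independent of the exposures. The
analyst, however, dichotomizes both exposures at a common cut point $c$,
$\tilde X_j = I(X_j > c)$ coded 0/1, and fits the saturated model in the two
indicators and their product. Because that design is a saturated $2 \times 2$,
its population coefficients are exact contrasts of the four cell means
$\mu_{ij} = E(Y \mid \tilde X_1 = i, \tilde X_2 = j)$; the product-term
coefficient is the double difference
$\tilde\beta_3 = \mu_{11} - \mu_{01} - \mu_{10} + \mu_{00}$. Any nonzero
$\tilde\beta_3$ is *induced by the categorization alone* — that is the sense
of "spurious" used in this package.

The cell means only require the truncated conditional expectations
$E(X_1 \mid \tilde X_1 = i, \tilde X_2 = j)$, for which closed forms exist in
the bivariate normal case (`quadrant_means()`): the upper-quadrant identity

$$F_{11}\, E(X_1 \mid X_1 > c, X_2 > c)
 = \varphi(c)\left[1 - \Phi\!\left(\frac{c - \rho c}{\sqrt{1-\rho^2}}\right)\right](1+\rho),$$

plus two recursions that express the mixed quadrants through
$\varphi(c)$ and $\rho\varphi(c)$, with the last quadrant recovered from the
law of total expectation. Conditional means of $X_2$ follow by exchange
symmetry (swap the indicator indices). Rearranging the double difference
gives a single expression proportional to
$(\beta_1+\beta_2)(1+\rho)\varphi(c)$ times a bracket in the orthant
probabilities (`interaction_contrast()`); its zero set is exactly
$\rho = 0$, $c = 0$, or $\beta_1 = -\beta_2$. `zero_interaction_roots()`
verifies this numerically: a 400-point sign scan over the requested cut
range followed by Brent root polishing to $10^{-8}$, with an
"identically zero" flag (scan maximum below $10^{-10}$) for the degenerate
configurations rather than a list of every grid point.

## Numerical choices

* **Orthant probabilities.** The upper orthant $F_{11}$ comes from
  `mvtnorm::pmvnorm()` with the deterministic bivariate algorithm
  (`TVPACK`, absolute tolerance $10^{-14}$); the other quadrants follow from
  the marginals, so normalization is exact by construction.
* **Underflow guard.** If any quadrant mass falls below $10^{-12}$
  (cut points beyond roughly $\pm 5$ SD, or strongly negative correlation at
  extreme cuts), the conditional-mean recursions would divide noise by
  noise; the package raises an error instead of returning values.
* **Independent oracle.** `quadrant_means_numeric()` recomputes all quadrant
  probabilities and means by nested adaptive 1-D quadrature of the joint
  density (`stats::integrate()` over both coordinates, the inner integral
  evaluated numerically rather than through $\Phi$), sharing no algebra with
  the closed forms. The test suite requires agreement to $10^{-6}$ over a
  correlation/cut grid; in practice agreement is near machine precision. The
  oracle also covers unequal cut points, which the closed forms do not.
* **No special-casing.** $\rho = 0$ and $c = 0$ go through the same code
  path as every other value; $(c - \rho c)/\sqrt{1 - \rho^2}$ is well defined
  for all $|\rho| < 1$.

## The simulation engine and what it emulates

`reproduce_tables()` re-runs the full factorial study that demonstrates the
effect empirically: three marginal families — standard normal, uniform on
$[0,1]$, and $\chi^2_2$ — crossed with observed correlations
$\rho \in \{0.2, 0.5, 0.7\}$ and cut percentiles 60% and 80%, with unit
slopes; plus two follow-ups at $\rho = 0.7$, 80th percentile (both slopes
doubled, and the second slope set to zero). The defaults are the study
conditions: 1000 replicates of $n = 10{,}000$ per cell, with
$\beta_0 = 0$.

Design choices that needed deciding:

* **Correlated non-normal pairs** come from a Gaussian copula: a latent
  normal pair is pushed through $\Phi$ (uniform) and then $-2\ln V$
  ($\chi^2_2$). The transforms attenuate Pearson correlation, so
  `calibrate_latent_rho()` finds the latent correlation whose *observed*
  correlation hits the target, by monotone bisection on one fixed calibration
  sample of $10^6$ pairs (common random numbers make the objective
  deterministic and monotone), to tolerance 0.002. For uniform marginals the
  closed form $\rho_{obs} = (6/\pi)\arcsin(\rho_{lat}/2)$ seeds the bracket;
  for normal marginals the transform is the identity and no sampling is done.
* **Residual variance** is set per family so that
  $\mathrm{Corr}(Y, X_1) = 0.3$ at $\rho = 0.5$ with unit slopes
  (`sigma2_for_target_corr()`: 22, 22/12 and 88 for the three families), and
  is then held fixed while $\rho$ varies and in the follow-up scenarios.
  Coefficient *means* do not involve $\sigma^2$ (they are cell-mean
  contrasts), only the replicate SDs do; the tests assert this invariance.
* **Cut points** are per-replicate *sample* percentiles by default
  (`cut_method = "empirical"`). We examined both conventions: for normal and
  uniform marginals they are indistinguishable at $n = 10{,}000$, while for
  the skewed $\chi^2_2$ the sample-percentile convention tracks the study's
  reported cells slightly better, and it is also what an analyst cutting "at
  the 60th percentile" of their data actually does. The
  `"theoretical"` option keeps the estimand exactly equal to the analytic
  contrast and is used in the test that ties simulation to closed forms.
* **Saturated fits** use the exact cell-mean reparameterization
  (`ols_saturated()`, one pass over the data); `stats::lm()` serves as the
  independent reference in the tests, never as the engine. Replicates with
  an empty indicator cell — possible in principle at extreme cuts — are
  retried under a fresh sub-seed, counted, and the run aborts if more than
  1% of replicates needed retries.
* **Seeding.** Every replicate derives its own seed from the scenario seed
  through a Lehmer-step stream, so any cell (and any single replicate) is
  reproducible in isolation; identical scenarios give bit-identical results.
* **Variants.** `dichotomize_x2 = FALSE` keeps the second exposure
  continuous (one-sided categorization) and `n_categories = k` cuts both
  exposures into $k$ equal-probability groups; both still induce interaction,
  which the tests demonstrate. These are demonstration options only — no
  analytic forms are provided for them.

What the generator does *not* emulate: real exposures are not exactly
normal/uniform/chi-square, their correlation structure is not exactly a
Gaussian copula, and real analyses choose cut points for substantive reasons
rather than fixed percentiles. Passing tests show the categorization
artefact and its sign/ordering structure under these controlled conditions;
they do not quantify the artefact for any particular real dataset.

## Reliability diagnostics

Dichotomization is an extreme form of measurement error. Its severity is the
point-biserial correlation between the continuous variable and its own
indicator: $h/\sqrt{pq}$ for a normal marginal
(`point_biserial_normal()`, maximal at the median cut), and the empirical
Pearson correlation for arbitrary samples (`empirical_point_biserial()`).
The key diagnostic is `stratified_reliability()`: the reliability of
$\tilde X_1$ computed within the two categories of $\tilde X_2$. When the two
strata differ, the measurement error is *differential*, and the stratum with
more error (lower reliability) determines the sign of the induced
interaction: for normal and uniform marginals reliability is lower in the
low-$\tilde X_2$ stratum and the induced interaction is negative; for the
right-skewed $\chi^2_2$ the pattern — and the sign — reverse. The stratified
estimator is always empirical, since no closed form is attempted within
strata; the closed form is offered for the marginal normal case only.

## Category collapsing on the relative-risk scale

The same mechanism appears in categorical data when exposure categories are
merged to save parameters. `stratified_count_table()`, `relative_risks()`,
`collapse_table()` and `interaction_check()` implement the demonstration:
the bundled table (`inst/extdata/collapse_demo.csv`) has relative risks
1, 2, 3, 4 in both strata — perfectly homogeneous, no interaction — yet
merging categories {1,2} and {3,4} yields RRs of 7/3 ≈ 2.33 in one stratum
and 15/7 ≈ 2.14 in the other, because the strata weight the merged
categories differently. Risks and RRs are kept as exact count fractions;
rounding (2 decimals) happens only at display. The homogeneity check flags
any max/min RR ratio above $1 + 10^{-9}$ by default — any inhomogeneity
beyond numerical noise is reported, with no significance testing attached,
since the demonstration is deterministic.

## Problem sizes and determinism

The package's own test suite runs the full-scale study (24 cells of
1000 × 10,000) in a few minutes on one CPU; unit tests use smaller scenario
sizes (tens of replicates of a few thousand observations) chosen so that the
checked quantities have Monte-Carlo errors comfortably inside the asserted
tolerances. Copula calibration uses $10^6$ pairs except in smoke tests.
All stochastic results are reproducible from a single base seed, including
the calibration stage.

## Known limitations

* The closed forms cover the equal-cut bivariate-normal case only; other
  marginals and unequal cuts are handled by simulation and by the quadrature
  oracle respectively.
* The induced-interaction theory is developed for the linear model; for
  nonlinear links (e.g. logistic regression) the same mechanism operates but
  is not treated analytically here.
* Interaction is scale-dependent: a model additive on one measurement scale
  can show interaction on another. The package quantifies the categorization
  artefact on the scale of the fitted linear model; it does not adjudicate
  which scale is substantively right.
* No efficiency or power analysis for interaction tests is included; the
  replicate SDs reported by the simulation engine are descriptive.
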