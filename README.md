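# spurint

Spurious interaction induced by categorizing continuous exposures.

## The problem

Epidemiological and clinical analyses routinely convert continuous exposures
(BMI, blood pressure, nutrient intake) into categories before fitting a
regression model. When two *correlated* exposures X₁, X₂ are dichotomized and
entered into a linear model together with their product, a non-zero
product-term coefficient appears **even though the true model has no
interaction at all**. `spurint` provides the analytic machinery for this
effect in the bivariate-normal case, a Monte-Carlo engine that demonstrates
it under normal, uniform and chi-square(2) marginals, reliability diagnostics
that explain its sign as differential measurement error, and
contingency-table tools showing the analogous artefact of *collapsing*
exposure categories on the relative-risk scale.

It is aimed at biostatisticians and methods-minded epidemiologists who want
to quantify — not just assert — how much interaction a given categorization
scheme can manufacture.

## The model

The true data-generating model is linear with no interaction:

    Y = β₀ + β₁X₁ + β₂X₂ + ε,   (X₁, X₂) ~ N(0, Σ),  Σ = [[1, ρ], [ρ, 1]],

with ε ~ N(0, σ²) independent of the exposures. Both exposures are
dichotomized at a common cut point c: X̃ⱼ = I(Xⱼ > c), coded 0/1. Fitting the
saturated model

    Y = β̃₀ + β̃₁X̃₁ + β̃₂X̃₂ + β̃₃X̃₁X̃₂ + ε̃

gives population coefficients that are exact contrasts of the four cell means
μᵢⱼ = E(Y | X̃₁ = i, X̃₂ = j); in particular the induced interaction is

    β̃₃ = μ₁₁ − μ₀₁ − μ₁₀ + μ₀₀.

The cell means follow from truncated bivariate-normal conditional
expectations, e.g.

    F₁₁ · E(X₁ | X₁>c, X₂>c) = φ(c) [1 − Φ((c − ρc)/√(1−ρ²))] (1+ρ),

where F₁₁ is the upper orthant probability and φ, Φ the standard-normal
density and CDF. The induced interaction vanishes **only** when ρ = 0
(uncorrelated exposures), c = 0 (median split), or β₁ = −β₂; any other
categorization manufactures interaction, growing rapidly with |c| and ρ.

## Worked example

Dichotomizing at the 80th percentile with correlation ρ = 0.7 and unit
slopes:

```r
library(spurint)
spec <- bivariate_spec(rho = 0.7, c = qnorm(0.8))
induced_coefficients(true_model(beta1 = 1, beta2 = 1), spec)
#>       bt0       bt1       bt2       bt3
#> -0.852078  2.362015  2.362015 -0.821314
```

The fitted indicator effects are about 2.36 — not 1, because each indicator
carries the conditional mean of its own exposure *and* of its correlated
partner — and an interaction of −0.82 appears out of nowhere: about 35% of a
main effect (`interaction_ratio(...)` returns 0.348). Root-finding confirms
the median split is the only cut that avoids this:

```r
zero_interaction_roots(true_model(beta1 = 1, beta2 = 1), 0.5, c(-2, 2))
#> $roots
#> [1] 8.84709e-17      # c = 0, to root tolerance
#> $identically_zero
#> [1] FALSE
```

A Monte-Carlo check of the same design (200 replicates of n = 10,000,
Y = X₁ + X₂ + N(0, 22)) recovers the analytic values:

```r
s <- scenario(distribution_spec("normal"), 0.7, 0.8,
              true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
              n = 10000, reps = 200, seed = 1)
run_scenario(s)
#> normal marginals, rho = 0.7, cut at 80 pct, n = 10000, reps = 200
#>         bt0   bt1   bt2    bt3
#> mean -0.856 2.357 2.371 -0.826
#> sd    0.062 0.173 0.167  0.254
```

The same artefact appears on the relative-risk scale when exposure
categories are collapsed. The bundled demonstration table has identical
relative risks 1, 2, 3, 4 in both strata (no interaction); merging categories
{1,2} and {3,4} breaks the homogeneity:

```r
cmd_collapse()
#> -- after collapsing --
#>  stratum category diseased total   risk   rr
#>        1        1       50   700 0.0714 1.00
#>        1        2       50   300 0.1667 2.33
#>        2        1       25   300 0.0833 1.00
#>        2        2      125   700 0.1786 2.14
#> relative risks differ across strata: interaction on the RR scale
```

`reproduce_tables()` runs the full simulation study (3 marginals × 3
correlations × 2 cut percentiles, plus the doubled-slope and zero-slope
follow-ups; 1000 replicates of n = 10,000 per cell), and
`cmd_theory()` / `cmd_reliability()` write the theory curves and the
point-biserial reliability diagnostics as commented CSV files. A thin
command-line front end is included at `inst/cli/spurint.R`.

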