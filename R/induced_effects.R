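#' True linear model for the continuous exposures
#'
#' The data-generating regression \eqn{Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2
#' + \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2)} independent of the
#' exposures. There is no interaction in this model; any product-term
#' coefficient that appears after dichotomization is induced by the
#' categorization alone.
#'
#' @param beta0 Intercept (response units).
#' @param beta1,beta2 Slopes per unit of the continuous exposures.
#' @param sigma2 Residual variance (>= 0). Irrelevant to the induced cell
#'   means; used by the simulation engine.
#'
#' @return An object of class `"true_model"`.
#' @examples
#' true_model(beta1 = 1, beta2 = 1, sigma2 = 22)
#' @export
true_model <- function(beta0 = 0, beta1 = 1, beta2 = 1, sigma2 = 0) {
  stopifnot(is.numeric(beta0), is.numeric(beta1), is.numeric(beta2),
            is.numeric(sigma2), length(sigma2) == 1L)
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  structure(list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
                 beta2 = as.numeric(beta2), sigma2 = as.numeric(sigma2)),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf("Y = %g + %g X1 + %g X2 + e,  Var(e) = %g\n",
              x$beta0, x$beta1, x$beta2, x$sigma2))
  invisible(x)
}

#' Expected response in each dichotomized cell
#'
#' Cell means \eqn{\mu_{ij} = E(Y \mid \tilde X_1 = i, \tilde X_2 = j)} under
#' the true linear model:
#' \eqn{\mu_{ij} = \beta_0 + \beta_1 E(X_1 \mid ij) + \beta_2 E(X_2 \mid ij)},
#' the conditional means of \eqn{X_2} being obtained from those of \eqn{X_1}
#' by the quadrant symmetry (swap the indicator indices).
#'
#' @param model A [true_model()].
#' @param spec A [bivariate_spec()].
#'
#' @return An object of class `"cell_means"`: list with `mu00`, `mu01`,
#'   `mu10`, `mu11` (response units).
#' @examples
#' cell_means(true_model(beta1 = 1, beta2 = 1), bivariate_spec(0, 0))
#' @export
cell_means <- function(model, spec) {
  stopifnot(inherits(model, "true_model"), inherits(spec, "bivariate_spec"))
  qm <- quadrant_means(spec)
  b0 <- model$beta0; b1 <- model$beta1; b2 <- model$beta2
  structure(list(
    mu00 = b0 + (b1 + b2) * qm$E00,
    mu01 = b0 + b1 * qm$E01 + b2 * qm$E10,
    mu10 = b0 + b1 * qm$E10 + b2 * qm$E01,
    mu11 = b0 + (b1 + b2) * qm$E11
  ), class = "cell_means")
}

#' Coefficients induced in the saturated dichotomized model
#'
#' Fitting \eqn{Y = \tilde\beta_0 + \tilde\beta_1 \tilde X_1 + \tilde\beta_2
#' \tilde X_2 + \tilde\beta_3 \tilde X_1 \tilde X_2 + \tilde\varepsilon}
#' with 0/1-coded indicators is a saturated 2x2 parameterization, so the
#' population coefficients are exact contrasts of the cell means:
#' \eqn{\tilde\beta_0 = \mu_{00}}, \eqn{\tilde\beta_1 = \mu_{10} - \mu_{00}},
#' \eqn{\tilde\beta_2 = \mu_{01} - \mu_{00}},
#' \eqn{\tilde\beta_3 = \mu_{11} - \mu_{01} - \mu_{10} + \mu_{00}}.
#' A nonzero `bt3` is the spurious interaction: the true model has none.
#'
#' @inheritParams cell_means
#' @return An object of class `"induced_coefficients"`: list with `bt0`,
#'   `bt1`, `bt2`, `bt3` (response units).
#' @examples
#' # median split kills the induced interaction, whatever the correlation:
#' induced_coefficients(true_model(beta1 = 1, beta2 = 1),
#'                      bivariate_spec(0.5, 0))$bt3
#' @export
induced_coefficients <- function(model, spec) {
  mu <- cell_means(model, spec)
  structure(list(
    bt0 = mu$mu00,
    bt1 = mu$mu10 - mu$mu00,
    bt2 = mu$mu01 - mu$mu00,
    bt3 = mu$mu11 - mu$mu01 - mu$mu10 + mu$mu00
  ), class = "induced_coefficients")
}

#' @export
print.induced_coefficients <- function(x, digits = 6, ...) {
  v <- round(c(bt0 = x$bt0, bt1 = x$bt1, bt2 = x$bt2, bt3 = x$bt3), digits)
  print(v)
  invisible(x)
}

#' Induced interaction via the direct orthant-probability expression
#'
#' Evaluates the induced interaction contrast
#' \eqn{\mu_{11} - \mu_{01} - \mu_{10} + \mu_{00}} directly as
#' \deqn{(\beta_1+\beta_2)(1+\rho)\varphi(c)\left[
#'   \frac{1-\Phi(a)}{F_{11}} - \frac{\Phi(a)}{F_{00}}
#'   - \frac{2\Phi(a)-1}{F_{01}}\right],
#'   \quad a = \frac{c-\rho c}{\sqrt{1-\rho^2}},}
#' an algebraic rearrangement of the cell-mean contrast that makes the zero
#' set visible: the contrast vanishes iff \eqn{\rho = 0}, \eqn{c = 0} or
#' \eqn{\beta_1 = -\beta_2}. Must agree with
#' `induced_coefficients(model, spec)$bt3` to numerical precision.
#'
#' @inheritParams cell_means
#' @return The interaction contrast (response units).
#' @examples
#' interaction_contrast(true_model(beta1 = 1, beta2 = 1),
#'                      bivariate_spec(0.7, qnorm(0.8)))
#' @export
interaction_contrast <- function(model, spec) {
  stopifnot(inherits(model, "true_model"), inherits(spec, "bivariate_spec"))
  F <- quadrant_probabilities(spec)
  rho <- spec$rho; c <- spec$c
  a <- (c - rho * c) / sqrt(1 - rho^2)
  Phi_a <- stats::pnorm(a)
  (model$beta1 + model$beta2) * (1 + rho) * stats::dnorm(c) *
    ((1 - Phi_a) / F$F11 - Phi_a / F$F00 - (2 * Phi_a - 1) / F$F01)
}

#' Relative size of the induced interaction
#'
#' The absolute ratio of the induced product-term coefficient to the induced
#' main effect of the second indicator, \eqn{|\tilde\beta_3 / \tilde\beta_2|}.
#' With \eqn{\beta_1 = \beta_2} the ratio to \eqn{\tilde\beta_1} is identical.
#'
#' @inheritParams cell_means
#' @return Non-negative scalar (dimensionless).
#' @examples
#' interaction_ratio(true_model(beta1 = 1, beta2 = 1),
#'                   bivariate_spec(0.5, 1))
#' @export
interaction_ratio <- function(model, spec) {
  ic <- induced_coefficients(model, spec)
  if (abs(ic$bt2) < 1e-12) {
    stop("main effect bt2 is numerically zero: ratio undefined",
         call. = FALSE)
  }
  abs(ic$bt3 / ic$bt2)
}

#' Induced main effect as a function of the cut point
#'
#' Evaluates \eqn{\tilde\beta_2(c) = \mu_{01} - \mu_{00}} over a grid of cut
#' points at fixed correlation: the apparent effect of the second dichotomized
#' exposure grows with more extreme cuts and stronger correlation.
#'
#' @param model A [true_model()].
#' @param rho Correlation, |rho| < 1.
#' @param c_grid Numeric vector of cut points.
#'
#' @return Numeric vector of `bt2` values, one per grid point.
#' @examples
#' main_effect_curve(true_model(beta1 = 1, beta2 = 1), 0.5, seq(0, 1.5, 0.5))
#' @export
main_effect_curve <- function(model, rho, c_grid) {
  stopifnot(is.numeric(c_grid), length(c_grid) >= 1L)
  vapply(c_grid,
         function(cc) induced_coefficients(model, bivariate_spec(rho, cc))$bt2,
         numeric(1))
}

#' Cut points at which the induced interaction vanishes
#'
#' Scans \eqn{\tilde\beta_3(c)} over `c_range` on a fine grid, then polishes
#' each sign change with [stats::uniroot()]. For normal marginals and
#' \eqn{\rho \ne 0}, \eqn{\beta_1 \ne -\beta_2}, the only root is the median
#' cut \eqn{c = 0}. When the contrast is identically zero over the scan grid
#' (\eqn{\rho = 0} or \eqn{\beta_1 = -\beta_2}) the result is flagged instead
#' of returning every grid point.
#'
#' @param model A [true_model()].
#' @param rho Correlation, |rho| < 1.
#' @param c_range Length-2 numeric interval to search.
#' @param n_grid Number of scan points (default 400).
#' @param tol Root tolerance passed to [stats::uniroot()].
#'
#' @return A list with `roots` (numeric vector, possibly empty) and
#'   `identically_zero` (logical flag).
#' @examples
#' zero_interaction_roots(true_model(beta1 = 1, beta2 = 1), 0.5, c(-2, 2))
#' @export
zero_interaction_roots <- function(model, rho, c_range = c(-2, 2),
                                   n_grid = 400L, tol = 1e-8) {
  stopifnot(length(c_range) == 2L, all(is.finite(c_range)),
            c_range[1] < c_range[2])
  f <- function(cc) interaction_contrast(model, bivariate_spec(rho, cc))
  grid <- seq(c_range[1], c_range[2], length.out = n_grid)
  fv <- vapply(grid, f, numeric(1))
  if (max(abs(fv)) < 1e-10) {
    return(list(roots = numeric(0), identically_zero = TRUE))
  }
  roots <- numeric(0)
  for (k in seq_len(n_grid - 1L)) {
    if (fv[k] == 0) roots <- c(roots, grid[k])
    else if (fv[k] * fv[k + 1L] < 0) {
      r <- stats::uniroot(f, c(grid[k], grid[k + 1L]), tol = tol)
      roots <- c(roots, r$root)
    }
  }
  if (length(fv) && fv[n_grid] == 0) roots <- c(roots, grid[n_grid])
  # merge duplicates produced by an exact grid hit adjacent to a sign change
  if (length(roots) > 1L) {
    roots <- sort(roots)
    roots <- roots[c(TRUE, diff(roots) > 10 * tol)]
  }
  list(roots = roots, identically_zero = FALSE)
}

#' Grid of induced coefficients over correlation and cut point
#'
#' Tabulates the induced coefficients and the interaction ratio over a
#' (rho, c) grid — the numeric content of the theory curves.
#'
#' @param model A [true_model()].
#' @param rhos Numeric vector of correlations.
#' @param c_grid Numeric vector of cut points.
#'
#' @return A data frame with columns `rho`, `c`, `bt0`, `bt1`, `bt2`, `bt3`,
#'   `ratio_bt3_bt2` (`NA` where `bt2` is numerically zero).
#' @examples
#' theory_grid(true_model(beta1 = 1, beta2 = 1), c(0.2, 0.5), c(0, 0.5, 1))
#' @export
theory_grid <- function(model, rhos = c(0.2, 0.5, 0.7),
                        c_grid = seq(-2, 2, by = 0.05)) {
  cells <- expand.grid(c = c_grid, rho = rhos)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- bivariate_spec(cells$rho[i], cells$c[i])
    ic <- induced_coefficients(model, sp)
    ratio <- if (abs(ic$bt2) < 1e-12) NA_real_ else abs(ic$bt3 / ic$bt2)
    data.frame(rho = cells$rho[i], c = cells$c[i],
               bt0 = ic$bt0, bt1 = ic$bt1, bt2 = ic$bt2, bt3 = ic$bt3,
               ratio_bt3_bt2 = ratio)
  })
  do.call(rbind, rows)
}
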