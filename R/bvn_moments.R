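#' Bivariate-normal dichotomization specification
#'
#' Describes a standard bivariate normal pair \eqn{(X_1, X_2)} with
#' correlation `rho`, both components dichotomized at the common cut point
#' `c` on the standard-normal scale (indicators \eqn{I(X_j > c)}).
#'
#' @param rho Pearson correlation, strictly inside (-1, 1). The boundary
#'   values are degenerate (the pair collapses onto a line) and are rejected.
#' @param c Common cut point, finite, in standard-deviation units.
#'
#' @return An object of class `"bivariate_spec"`.
#' @examples
#' bivariate_spec(rho = 0.5, c = qnorm(0.8))
#' @export
bivariate_spec <- function(rho, c) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (abs(rho) >= 1) {
    stop("degenerate correlation: |rho| must be strictly less than 1",
         call. = FALSE)
  }
  structure(list(rho = as.numeric(rho), c = as.numeric(c)),
            class = "bivariate_spec")
}

#' @export
print.bivariate_spec <- function(x, ...) {
  cat(sprintf("bivariate normal dichotomization: rho = %g, cut = %g\n",
              x$rho, x$c))
  invisible(x)
}

# Smallest quadrant probability tolerated before the conditional-mean
# identities start dividing by numerical noise.
.F_UNDERFLOW <- 1e-12

#' Quadrant probabilities of a dichotomized bivariate normal
#'
#' Probabilities that the standard bivariate normal pair falls in each of the
#' four quadrants defined by the common cut point: \eqn{F_{ij}} with
#' \eqn{i = I(X_1 > c)}, \eqn{j = I(X_2 > c)}.
#'
#' The upper orthant is computed with [mvtnorm::pmvnorm()]; the remaining
#' quadrants follow from the marginals, so the four values sum to one by
#' construction up to the orthant routine's tolerance.
#'
#' @param spec A [bivariate_spec()].
#'
#' @return An object of class `"quadrant_probabilities"`: a list with
#'   numeric elements `F00`, `F01`, `F10`, `F11`.
#' @examples
#' quadrant_probabilities(bivariate_spec(0.5, 0)) # F11 = 1/3, F01 = 1/6
#' @export
quadrant_probabilities <- function(spec) {
  stopifnot(inherits(spec, "bivariate_spec"))
  rho <- spec$rho; c <- spec$c
  corr <- matrix(c(1, rho, rho, 1), 2L, 2L)
  F11 <- as.numeric(mvtnorm::pmvnorm(
    lower = c(c, c), upper = c(Inf, Inf), corr = corr,
    algorithm = mvtnorm::TVPACK(1e-14)))
  p_hi <- stats::pnorm(c, lower.tail = FALSE)
  F10 <- p_hi - F11
  F01 <- F10                       # equal cut points: symmetric quadrants
  F00 <- 1 - F11 - F10 - F01
  out <- list(F00 = F00, F01 = F01, F10 = F10, F11 = F11)
  if (any(unlist(out) < .F_UNDERFLOW)) {
    stop("quadrant probability underflow: a quadrant has mass below 1e-12 ",
         "(cut point too extreme for stable conditional means)",
         call. = FALSE)
  }
  structure(out, class = "quadrant_probabilities")
}

#' Conditional mean of X1 in the upper quadrant
#'
#' Closed form for \eqn{E(X_1 \mid X_1 > c, X_2 > c)} of a standard bivariate
#' normal:
#' \deqn{E_{11} = \varphi(c)\,[1 - \Phi((c - \rho c)/\sqrt{1-\rho^2})]\,(1+\rho) / F_{11}.}
#'
#' @inheritParams quadrant_probabilities
#' @return The conditional expectation (standard-normal units).
#' @examples
#' upper_quadrant_mean(bivariate_spec(0, 0)) # sqrt(2/pi), half-normal mean
#' @export
upper_quadrant_mean <- function(spec) {
  stopifnot(inherits(spec, "bivariate_spec"))
  F <- quadrant_probabilities(spec)
  rho <- spec$rho; c <- spec$c
  a <- (c - rho * c) / sqrt(1 - rho^2)
  stats::dnorm(c) * stats::pnorm(a, lower.tail = FALSE) * (1 + rho) / F$F11
}

#' Conditional means of X1 in all four quadrants
#'
#' Truncated conditional expectations \eqn{E_{ij} = E(X_1 \mid \tilde X_1 = i,
#' \tilde X_2 = j)} of the standard bivariate normal, from the closed-form
#' upper-quadrant mean and the recursion
#' \eqn{F_{10}E_{10} = \varphi(c) - F_{11}E_{11}},
#' \eqn{F_{01}E_{01} = \rho\varphi(c) - F_{11}E_{11}}, with \eqn{E_{00}}
#' recovered from the law of total expectation (\eqn{E X_1 = 0}).
#'
#' Conditional means of \eqn{X_2} follow by symmetry:
#' \eqn{E(X_2 \mid \tilde X_1 = i, \tilde X_2 = j) = E(X_1 \mid \tilde X_1 = j,
#' \tilde X_2 = i)}.
#'
#' @inheritParams quadrant_probabilities
#' @return An object of class `"quadrant_means"`: list with elements `E00`,
#'   `E01`, `E10`, `E11` and the `"quadrant_probabilities"` in `F`.
#' @examples
#' qm <- quadrant_means(bivariate_spec(0.5, qnorm(0.6)))
#' with(qm, F$F00 * E00 + F$F01 * E01 + F$F10 * E10 + F$F11 * E11) # ~0
#' @export
quadrant_means <- function(spec) {
  stopifnot(inherits(spec, "bivariate_spec"))
  F <- quadrant_probabilities(spec)
  rho <- spec$rho; c <- spec$c
  phi_c <- stats::dnorm(c)
  E11 <- upper_quadrant_mean(spec)
  E10 <- (phi_c - F$F11 * E11) / F$F10
  E01 <- (rho * phi_c - F$F11 * E11) / F$F01
  E00 <- (0 - F$F11 * E11 - F$F01 * E01 - F$F10 * E10) / F$F00
  structure(list(E00 = E00, E01 = E01, E10 = E10, E11 = E11, F = F),
            class = "quadrant_means")
}

#' @export
print.quadrant_means <- function(x, digits = 6, ...) {
  m <- rbind(F = unlist(x$F),
             E = c(x$E00, x$E01, x$E10, x$E11))
  colnames(m) <- c("(0,0)", "(0,1)", "(1,0)", "(1,1)")
  cat("quadrant probabilities and conditional means of X1\n")
  print(round(m, digits))
  invisible(x)
}

#' Quadrant probabilities and means by 2-D quadrature
#'
#' Independent numerical route to the quadrant quantities: nested adaptive
#' quadrature ([stats::integrate()] over both coordinates) of the bivariate
#' normal density (and of \eqn{x \times} density) over each quadrant. The
#' inner integral over the second coordinate is evaluated numerically, so the
#' route shares no algebra with the closed forms. Supports unequal cut points
#' `c1`, `c2`, which the closed forms do not cover.
#'
#' Intended as a cross-check oracle for [quadrant_means()]; it is orders of
#' magnitude slower than the closed forms.
#'
#' @param rho Correlation, |rho| < 1.
#' @param c1,c2 Cut points for `X1` and `X2`.
#' @param tol Quadrature tolerance (relative, both levels); failure to reach
#'   it is reported with the achieved estimate of accuracy.
#'
#' @return An object of class `"quadrant_means"` (same shape as
#'   [quadrant_means()]).
#' @examples
#' quadrant_means_numeric(0.5, 0, 0)
#' @export
quadrant_means_numeric <- function(rho, c1, c2, tol = 1e-10) {
  stopifnot(is.numeric(rho), length(rho) == 1L, abs(rho) < 1,
            is.finite(c1), is.finite(c2))
  s <- sqrt(1 - rho^2)
  quad <- function(weight_x, xa, xb, ya, yb) {
    inner <- function(x) {
      vapply(x, function(xx) {
        stats::integrate(function(y) stats::dnorm((y - rho * xx) / s) / s,
                         ya, yb, rel.tol = tol, abs.tol = 1e-14)$value
      }, numeric(1))
    }
    r <- stats::integrate(function(x) weight_x(x) * stats::dnorm(x) * inner(x),
                          xa, xb, rel.tol = tol, abs.tol = 1e-14)
    if (r$message != "OK") {
      stop("quadrature did not converge (", r$message,
           "); achieved abs.error ", format(r$abs.error), call. = FALSE)
    }
    r$value
  }
  bounds <- list(`00` = c(-Inf, c1, -Inf, c2),
                 `01` = c(-Inf, c1, c2, Inf),
                 `10` = c(c1, Inf, -Inf, c2),
                 `11` = c(c1, Inf, c2, Inf))
  one <- function(x) rep(1, length(x))
  F <- lapply(bounds, function(b) quad(one, b[1], b[2], b[3], b[4]))
  N <- lapply(bounds, function(b) quad(identity, b[1], b[2], b[3], b[4]))
  Fp <- structure(list(F00 = F$`00`, F01 = F$`01`,
                       F10 = F$`10`, F11 = F$`11`),
                  class = "quadrant_probabilities")
  structure(list(E00 = N$`00` / F$`00`, E01 = N$`01` / F$`01`,
                 E10 = N$`10` / F$`10`, E11 = N$`11` / F$`11`, F = Fp),
            class = "quadrant_means")
}
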