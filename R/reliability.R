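#' Point-biserial reliability of a dichotomized normal variable
#'
#' Pearson correlation between a standard normal variable and its own
#' indicator \eqn{I(X > c)}: \eqn{h / \sqrt{pq}}, where \eqn{h} is the normal
#' ordinate at the cut and \eqn{p, q} the probability masses above and below
#' it. This is the reliability of the dichotomized variable relative to the
#' continuous original; it is maximal at the median cut (\eqn{c = 0}) and
#' decays for more extreme cuts — dichotomization is an extreme form of
#' measurement error, and the more extreme the cut, the more error.
#'
#' @param c Cut point on the standard-normal scale (finite; vectorized).
#' @return Point-biserial correlation(s) in (0, 1).
#' @examples
#' point_biserial_normal(0)          # 2 * dnorm(0) = 0.7979
#' point_biserial_normal(qnorm(0.8)) # 0.6999
#' @export
point_biserial_normal <- function(c) {
  stopifnot(is.numeric(c), all(is.finite(c)))
  p <- stats::pnorm(c)
  stats::dnorm(c) / sqrt(p * (1 - p))
}

#' Empirical point-biserial correlation
#'
#' Sample Pearson correlation between a continuous sample and its indicator
#' \eqn{I(x > \mathrm{cut})}; the empirical counterpart of
#' [point_biserial_normal()], usable for any marginal distribution.
#'
#' @param x Numeric sample (length >= 2).
#' @param cut Threshold; both categories must be non-empty.
#' @return Correlation in \[-1, 1\].
#' @examples
#' set.seed(1)
#' empirical_point_biserial(rnorm(1e4), 0)
#' @export
empirical_point_biserial <- function(x, cut) {
  stopifnot(is.numeric(x), length(x) >= 2L, is.finite(cut))
  ind <- x > cut
  if (!any(ind) || all(ind)) {
    stop("degenerate sample: one dichotomization category is empty",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate sample: x is constant", call. = FALSE)
  }
  stats::cor(x, as.numeric(ind))
}

#' Reliability of one dichotomized exposure within strata of the other
#'
#' The measurement-error reading of the induced interaction: the reliability
#' (point-biserial correlation) of \eqn{\tilde X_1} is computed overall and
#' separately within the two categories of \eqn{\tilde X_2}. When the two
#' within-stratum reliabilities differ, the measurement error in \eqn{X_1} is
#' differential with respect to \eqn{X_2}, and an induced interaction between
#' the observed (dichotomized) versions is to be expected; the stratum with
#' the lower reliability determines its sign.
#'
#' @param x1,x2 Paired numeric samples.
#' @param cut1,cut2 Dichotomization thresholds for `x1` and `x2`.
#'
#' @return An object of class `"reliability_report"`: list with `overall`,
#'   `by_stratum` (named pair: `x2_low` for \eqn{\tilde X_2 = 0}, `x2_high`
#'   for \eqn{\tilde X_2 = 1}) and `cut` (the `cut1` used).
#' @examples
#' set.seed(1)
#' z1 <- rnorm(1e4); z2 <- 0.7 * z1 + sqrt(1 - 0.49) * rnorm(1e4)
#' stratified_reliability(z1, z2, qnorm(0.8), qnorm(0.8))
#' @export
stratified_reliability <- function(x1, x2, cut1, cut2) {
  stopifnot(is.numeric(x1), is.numeric(x2), length(x1) == length(x2),
            is.finite(cut1), is.finite(cut2))
  hi2 <- x2 > cut2
  check_stratum <- function(x, label) {
    if (length(x) < 2L || !any(x > cut1) || all(x > cut1)) {
      stop("degenerate stratum '", label,
           "': needs both x1 categories represented", call. = FALSE)
    }
  }
  check_stratum(x1[!hi2], "x2_low")
  check_stratum(x1[hi2], "x2_high")
  structure(list(
    overall = empirical_point_biserial(x1, cut1),
    by_stratum = c(x2_low  = empirical_point_biserial(x1[!hi2], cut1),
                   x2_high = empirical_point_biserial(x1[hi2], cut1)),
    cut = cut1
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 4, ...) {
  cat(sprintf("point-biserial reliability at cut %g\n", x$cut))
  cat(sprintf("  overall: %.*f\n", digits, x$overall))
  cat(sprintf("  within x2 low / high: %.*f / %.*f\n",
              digits, x$by_stratum[["x2_low"]],
              digits, x$by_stratum[["x2_high"]]))
  invisible(x)
}
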