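test_that("marginal specifications carry the analytic variances and
           quantiles", {
  expect_equal(distribution_spec("normal")$variance, 1)
  expect_equal(distribution_spec("uniform01")$variance, 1 / 12)
  expect_equal(distribution_spec("chisq2")$variance, 4)
  expect_equal(marginal_quantile(distribution_spec("normal"), 0.8),
               qnorm(0.8))
  expect_equal(marginal_quantile(distribution_spec("uniform01"), 0.6), 0.6)
  expect_equal(marginal_quantile(distribution_spec("chisq2"), 0.8),
               3.2188758, tolerance = 1e-7)
  # chi-square quantile inverts the survival function 1 - exp(-x/2)
  expect_equal(1 - exp(-marginal_quantile(distribution_spec("chisq2"), 0.6) / 2),
               0.6, tolerance = 1e-12)
})

test_that("copula calibration is exact for normal, matches the arcsine
           inversion for uniform, and attains the target for chi-square", {
  cal_n <- calibrate_latent_rho(distribution_spec("normal"), 0.5)
  expect_identical(cal_n$latent_rho, 0.5)
  cal_u <- calibrate_latent_rho(distribution_spec("uniform01"), 0.5,
                                n = 2e5, seed = 2)
  expect_true(cal_u$converged)
  expect_equal(cal_u$latent_rho, 2 * sin(pi * 0.5 / 6), tolerance = 0.02)
  expect_lte(abs(cal_u$achieved_rho - 0.5), cal_u$tolerance)
  cal_c <- calibrate_latent_rho(distribution_spec("chisq2"), 0.7,
                                n = 2e5, seed = 2)
  expect_true(cal_c$converged)
  expect_lte(abs(cal_c$achieved_rho - 0.7), cal_c$tolerance)
  expect_gt(cal_c$latent_rho, 0.7)     # transform attenuates, latent above
})

test_that("sampled exposures have the right marginals and correlation", {
  n <- 1e5
  dn <- distribution_spec("normal")
  xn <- sample_exposures(dn, calibrate_latent_rho(dn, 0.2), n, seed = 4)
  expect_lt(abs(cor(xn[, 1], xn[, 2]) - 0.2), 0.01)
  dc <- distribution_spec("chisq2")
  xc <- sample_exposures(dc, calibrate_latent_rho(dc, 0.5, n = 2e5, seed = 1),
                         n, seed = 4)
  expect_lt(abs(mean(xc[, 1]) - 2), 0.05)
  expect_lt(abs(var(xc[, 1]) - 4), 0.2)
  du <- distribution_spec("uniform01")
  xu <- sample_exposures(du, calibrate_latent_rho(du, 0.5, n = 2e5, seed = 1),
                         n, seed = 4)
  ks <- max(abs(sort(xu[, 1]) - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 0.01)
})

test_that("residual variance solves the response-exposure correlation", {
  m <- true_model(beta1 = 1, beta2 = 1)
  expect_equal(sigma2_for_target_corr(distribution_spec("normal"), m, 0.5, 0.3),
               22, tolerance = 1e-12)
  expect_equal(sigma2_for_target_corr(distribution_spec("uniform01"), m, 0.5,
                                      0.3), 22 / 12, tolerance = 1e-12)
  expect_equal(sigma2_for_target_corr(distribution_spec("chisq2"), m, 0.5, 0.3),
               88, tolerance = 1e-12)
  # Monte-Carlo check that the solved variance attains the correlation
  set.seed(9)
  dn <- distribution_spec("normal")
  x <- sample_exposures(dn, calibrate_latent_rho(dn, 0.5), 2e5)
  y <- x[, 1] + x[, 2] + rnorm(2e5, 0, sqrt(22))
  expect_lt(abs(cor(y, x[, 1]) - 0.3), 0.01)
  expect_error(sigma2_for_target_corr(distribution_spec("normal"), m, 0.5,
                                      0.99), "infeasible")
})

test_that("saturated 2x2 least squares equals the cell-mean identity and the
           reference OLS fit", {
  # exact identity on cell constants
  f <- ols_saturated(c(1, 2, 3, 7), c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(unlist(f[1:4]), c(bt0 = 1, bt1 = 1, bt2 = 2, bt3 = 3))
  # agreement with lm() on noisy data
  set.seed(21)
  x1b <- rbinom(500, 1, 0.4); x2b <- rbinom(500, 1, 0.3)
  y <- 0.5 + x1b - 2 * x2b + 0.7 * x1b * x2b + rnorm(500)
  ref <- unname(coef(lm(y ~ x1b + x2b + x1b:x2b)))
  expect_equal(unname(unlist(ols_saturated(y, x1b, x2b)[1:4])), ref,
               tolerance = 1e-10)
  expect_error(ols_saturated(c(1, 2), c(0, 0), c(0, 0)), "empty cell")
})

test_that("scenario runs are seed-deterministic and their means are
           noise-level invariant", {
  dn <- distribution_spec("normal")
  s <- scenario(dn, 0.5, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
                n = 2000, reps = 50, seed = 17)
  r1 <- run_scenario(s); r2 <- run_scenario(s)
  expect_identical(r1$mean_bt, r2$mean_bt)
  expect_identical(r1$sd_bt, r2$sd_bt)
  s_low <- scenario(dn, 0.5, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 11),
                    n = 2000, reps = 50, seed = 23)
  r_low <- run_scenario(s_low)
  tol <- 4 * sqrt(r1$mc_se^2 + r_low$mc_se^2)
  expect_true(all(abs(r1$mean_bt - r_low$mean_bt) < tol))
  expect_true(all(r_low$sd_bt < r1$sd_bt))
})

test_that("uncorrelated exposures yield no induced interaction", {
  dn <- distribution_spec("normal")
  s <- scenario(dn, 0, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
                n = 4000, reps = 200, seed = 3)
  r <- run_scenario(s)
  expect_lt(abs(r$mean_bt[["bt3"]]), 3 * r$mc_se[["bt3"]])
})

test_that("a zero slope on the second exposure still produces an apparent
           main effect and interaction", {
  dn <- distribution_spec("normal")
  s <- scenario(dn, 0.7, 0.8, true_model(beta1 = 1, beta2 = 0, sigma2 = 22),
                n = 4000, reps = 150, seed = 13)
  r <- run_scenario(s)
  expect_gt(r$mean_bt[["bt2"]], 5 * r$mc_se[["bt2"]])
  expect_lt(r$mean_bt[["bt3"]], -5 * r$mc_se[["bt3"]])
})

test_that("one-sided categorization and more than two categories also induce
           interaction", {
  dn <- distribution_spec("normal")
  s1 <- scenario(dn, 0.7, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
                 n = 4000, reps = 100, seed = 2, dichotomize_x2 = FALSE)
  r1 <- run_scenario(s1)
  expect_lt(r1$mean_bt[["bt3"]], -4 * r1$mc_se[["bt3"]])
  s3 <- scenario(dn, 0.7, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
                 n = 4000, reps = 100, seed = 2, n_categories = 3L)
  r3 <- run_scenario(s3)
  ints <- grepl(":", names(r3$mean_bt))
  expect_true(any(abs(r3$mean_bt[ints]) > 4 * r3$mc_se[ints]))
  expect_error(scenario(dn, 0.5, 0.8, true_model(), n_categories = 3L,
                        dichotomize_x2 = FALSE), "one-sided")
})

test_that("theoretical-cut scenarios recover the analytic contrasts", {
  dn <- distribution_spec("normal")
  s <- scenario(dn, 0.7, 0.8, true_model(beta1 = 1, beta2 = 1, sigma2 = 22),
                n = 10000, reps = 150, seed = 31,
                cut_method = "theoretical")
  r <- run_scenario(s)
  ic <- induced_coefficients(true_model(beta1 = 1, beta2 = 1),
                             bivariate_spec(0.7, qnorm(0.8)))
  for (cf in c("bt0", "bt1", "bt2", "bt3")) {
    expect_lt(abs(r$mean_bt[[cf]] - ic[[cf]]), 3 * r$mc_se[[cf]])
  }
})
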