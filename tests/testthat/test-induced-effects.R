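unit_model <- true_model(beta1 = 1, beta2 = 1)

test_that("cell means reduce correctly in the symmetric and null cases", {
  mu0 <- cell_means(true_model(beta1 = 0, beta2 = 0), bivariate_spec(0.4, 0.7))
  expect_equal(unlist(mu0[1:4]), c(mu00 = 0, mu01 = 0, mu10 = 0, mu11 = 0))
  mu <- cell_means(unit_model, bivariate_spec(0, 0))
  expect_equal(mu$mu00, -2 * sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(mu$mu11, 2 * sqrt(2 / pi), tolerance = 1e-10)
  expect_equal(mu$mu01, 0, tolerance = 1e-12)
  expect_equal(mu$mu10, 0, tolerance = 1e-12)
})

test_that("cell means agree with the quadrature oracle", {
  sp <- bivariate_spec(0.5, qnorm(0.6))
  qn <- quadrant_means_numeric(0.5, qnorm(0.6), qnorm(0.6))
  mu <- cell_means(unit_model, sp)
  expect_equal(mu$mu00, 2 * qn$E00, tolerance = 1e-6)
  expect_equal(mu$mu11, 2 * qn$E11, tolerance = 1e-6)
  expect_equal(mu$mu01, qn$E01 + qn$E10, tolerance = 1e-6)
  expect_equal(mu$mu10, qn$E01 + qn$E10, tolerance = 1e-6)
})

test_that("the induced interaction vanishes exactly on the zero manifold", {
  for (rho in c(0.2, 0.5, 0.7)) {
    expect_lt(abs(induced_coefficients(unit_model, bivariate_spec(rho, 0))$bt3),
              1e-10)
  }
  for (cc in c(0.25, 0.84, 1.28)) {
    expect_lt(abs(induced_coefficients(unit_model, bivariate_spec(0, cc))$bt3),
              1e-10)
  }
  opp <- true_model(beta1 = 1, beta2 = -1)
  expect_lt(abs(induced_coefficients(opp, bivariate_spec(0.5, 1))$bt3), 1e-10)
  # ... and is clearly nonzero off it
  expect_gt(abs(induced_coefficients(unit_model, bivariate_spec(0.5, 0.5))$bt3),
            1e-3)
})

test_that("induced interaction at strong correlation and extreme cut matches
           the study magnitude", {
  bt3 <- induced_coefficients(unit_model, bivariate_spec(0.7, qnorm(0.8)))$bt3
  expect_equal(bt3, -0.81, tolerance = 0.04)
})

test_that("cell-mean contrast and direct orthant expression agree everywhere", {
  grid <- expand.grid(rho = c(-0.7, -0.3, 0.3, 0.5, 0.7),
                      c = c(-2, -1, -0.5, 0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    sp <- bivariate_spec(grid$rho[i], grid$c[i])
    expect_equal(interaction_contrast(unit_model, sp),
                 induced_coefficients(unit_model, sp)$bt3, tolerance = 1e-9)
  }
  # negative sign for positive correlation and cut
  for (rho in c(0.2, 0.5, 0.7)) {
    for (cc in c(0.3, 0.8, 1.3)) {
      expect_lt(interaction_contrast(unit_model, bivariate_spec(rho, cc)), 0)
    }
  }
})

test_that("interaction contrast is linear in the slope sum", {
  sp <- bivariate_spec(0.6, 1.1)
  expect_equal(induced_coefficients(true_model(beta1 = 2, beta2 = 2), sp)$bt3,
               2 * induced_coefficients(unit_model, sp)$bt3,
               tolerance = 1e-12)
})

test_that("interaction ratio is zero at the median, grows with the cut and
           orders by correlation", {
  expect_equal(interaction_ratio(unit_model, bivariate_spec(0.5, 0)), 0,
               tolerance = 1e-10)
  cgrid <- seq(0, 1.6, by = 0.2)
  curves <- sapply(c(0.2, 0.5, 0.7), function(rho) {
    sapply(cgrid, function(cc)
      interaction_ratio(unit_model, bivariate_spec(rho, cc)))
  })
  for (j in 1:3) expect_true(all(diff(curves[, j]) >= -1e-10))
  expect_true(all(curves[-1, 3] > curves[-1, 1]))
  expect_error(interaction_ratio(true_model(beta1 = 0, beta2 = 0),
                                 bivariate_spec(0.5, 1)), "zero")
})

test_that("induced main effect grows with cut point and correlation", {
  cgrid <- seq(0, 1.5, by = 0.25)
  for (rho in c(0.2, 0.5, 0.7)) {
    bt2 <- main_effect_curve(unit_model, rho, cgrid)
    expect_true(all(diff(bt2) > 0))
  }
  for (cc in c(0.5, 1)) {
    by_rho <- sapply(c(0.2, 0.5, 0.7), function(rho)
      induced_coefficients(unit_model, bivariate_spec(rho, cc))$bt2)
    expect_true(all(diff(by_rho) > 0))
  }
  expect_equal(main_effect_curve(true_model(beta1 = 0, beta2 = 0), 0.5,
                                 c(0, 0.5, 1)), c(0, 0, 0))
  # closed-form value at c = 0: mu01 - mu00 = (E01 + E10) - 2 * E00
  qm <- quadrant_means(bivariate_spec(0.2, 0))
  expect_equal(main_effect_curve(unit_model, 0.2, 0),
               (qm$E01 + qm$E10) - 2 * qm$E00, tolerance = 1e-12)
})

test_that("zero-interaction root finding isolates the median cut or flags an
           identically zero contrast", {
  z <- zero_interaction_roots(unit_model, 0.5, c(-2, 2))
  expect_false(z$identically_zero)
  expect_length(z$roots, 1L)
  expect_lt(abs(z$roots), 1e-6)
  expect_true(zero_interaction_roots(unit_model, 0, c(-2, 2))$identically_zero)
  expect_true(zero_interaction_roots(true_model(beta1 = 1, beta2 = -1),
                                     0.5, c(-2, 2))$identically_zero)
  # no sign change away from zero: empty root set, not an error
  z2 <- zero_interaction_roots(unit_model, 0.5, c(0.2, 1.5))
  expect_false(z2$identically_zero)
  expect_length(z2$roots, 0L)
})

test_that("theory grid tabulates coefficients with the ratio column", {
  g <- theory_grid(unit_model, rhos = c(0.2, 0.5), c_grid = c(0, 0.5, 1))
  expect_equal(nrow(g), 6L)
  expect_named(g, c("rho", "c", "bt0", "bt1", "bt2", "bt3", "ratio_bt3_bt2"))
  expect_equal(g$ratio_bt3_bt2, abs(g$bt3 / g$bt2), tolerance = 1e-12)
})
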