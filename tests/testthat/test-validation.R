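test_that("normalized residuals: identities and input checks", {
  g <- decay_grid(ref$decay, span = 3, by = 0.5)
  ex <- expected_transient(g, ref$decay, ref$illumination, ref$acquisition)
  est <- estimate_transient(ex$series, ref$acquisition, method = "delta")
  expect_equal(normalized_residuals(est, ex$true_ca, se = "delta"),
               rep(0, nrow(est)))
  shifted <- ex$true_ca - est$se_delta
  expect_equal(normalized_residuals(est, shifted, se = "delta"),
               rep(1, nrow(est)))
  expect_error(normalized_residuals(est, ex$true_ca[-1], se = "delta"),
               class = "fura_invalid_input")
  expect_error(normalized_residuals(est, ex$true_ca, se = "mc"),
               class = "fura_invalid_input")  # no MC SEs computed
})

test_that("Shapiro-Wilk wrapper: delegation contract and power", {
  # reference agreement with the standard routine
  set.seed(21)
  x <- rnorm(150)
  got <- shapiro_wilk(x)
  want <- stats::shapiro.test(x)
  expect_equal(got$w, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  expect_error(shapiro_wilk(rep(1, 10)), class = "fura_invalid_input")
  expect_error(shapiro_wilk(rnorm(2)), class = "fura_invalid_input")
  # power sanity check: strongly skewed sample is rejected
  set.seed(22)
  expect_lt(shapiro_wilk(rexp(200))$p, 0.01)
})

test_that("Kolmogorov band: asymptotic quantiles and monotonicity", {
  # frozen asymptotic quantiles of the Kolmogorov distribution
  expect_equal(as.numeric(kolmogorov_band(1e5, 0.05)) * sqrt(1e5),
               1.35809863932, tolerance = 1e-6)
  expect_equal(as.numeric(kolmogorov_band(1e5, 0.01)) * sqrt(1e5),
               1.62762361152, tolerance = 1e-6)
  for (n in c(1, 10, 200, 5000))
    expect_gt(kolmogorov_band(n, 0.01), kolmogorov_band(n, 0.05))
  expect_error(kolmogorov_band(100, 0), class = "fura_invalid_input")
  expect_error(kolmogorov_band(100, 1), class = "fura_invalid_input")
})

test_that("exact finite-n band agrees with the reference KS distribution", {
  # oracle: stats::ks.test computes exact one-sample p-values; a sample
  # lies inside the alpha band iff its exact p-value exceeds alpha
  set.seed(23)
  for (i in 1:20) {
    n <- sample(c(10, 50, 200), 1)
    x <- rnorm(n, sd = sample(c(1, 1.5), 1))
    chk <- ecdf_band_check(x, alpha = 0.05, method = "exact")
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", exact = TRUE))
    expect_equal(chk$max_deviation, unname(ks$statistic))
    expect_identical(chk$inside, ks$p.value > 0.05)
  }
})

test_that("ECDF band check: boundary and shift detection", {
  one <- ecdf_band_check(0, alpha = 0.05)
  expect_equal(one$max_deviation, 0.5)
  expect_true(one$inside)   # n = 1 band is wide (half-width 0.975)
  set.seed(24)
  x <- rnorm(200)
  expect_false(ecdf_band_check(x + 1, alpha = 0.05)$inside)
  expect_true(ecdf_band_check(x, alpha = 0.01)$half_width >
                ecdf_band_check(x, alpha = 0.05)$half_width)
})

test_that("weighted monoexponential fit recovers exact model values", {
  g <- decay_grid(ref$decay, span = 20, by = 0.25)
  ca <- ca_timecourse(g, ref$decay)
  est <- structure(data.frame(time = g, ca = ca, se_delta = 1, se_mc = 1,
                              valid = TRUE),
                   class = c("fura_estimates", "data.frame"))
  fit <- fit_monoexp_weighted(est, t0 = ref$decay$t0, se = "delta")
  expect_equal(fit$estimate$ca0, 0.059, tolerance = 1e-6)
  expect_equal(fit$estimate$delta, 0.114, tolerance = 1e-6)
  expect_equal(fit$estimate$tau, 2.339, tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-10)
  expect_error(fit_monoexp_weighted(est[1:3, ], t0 = ref$decay$t0,
                                    se = "delta"),
               class = "fura_invalid_input")
})

test_that("full validation run is calibrated and reproducible", {
  r1 <- run_validation(seed = 31, k = 2000)
  r2 <- run_validation(seed = 31, k = 2000)
  expect_identical(r1$residuals, r2$residuals)
  n <- r1$n_points
  expect_equal(n, 201L)
  # standard-normal sampling bounds for ~200 points
  expect_lt(abs(r1$mean), 3 / sqrt(n))
  expect_gt(r1$sd, 0.8); expect_lt(r1$sd, 1.2)
  expect_gt(r1$sw_p, 0.01)
})

test_that("validation detects deliberately mis-scaled standard errors", {
  set.seed(33)
  sim <- simulate_transient(decay_grid(ref$decay), ref$decay,
                            ref$illumination, ref$acquisition)
  est <- estimate_transient(sim$series, ref$acquisition, method = "delta")
  res_ok <- normalized_residuals(est, sim$true_ca, se = "delta")
  est$se_delta <- est$se_delta / 2       # halved SEs: residual SD doubles
  res_half <- normalized_residuals(est, sim$true_ca, se = "delta")
  expect_equal(sd(res_half), 2 * sd(res_ok))
  expect_gt(sd(res_half), 1.6)
  est$se_delta <- est$se_delta * 4       # doubled SEs: residual SD halves
  res_twice <- normalized_residuals(est, sim$true_ca, se = "delta")
  expect_lt(sd(res_twice), 0.65)
})
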