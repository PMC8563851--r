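test_that("background-corrected flux matches direct arithmetic", {
  expect_equal(flux(300, 0, 0.01, 3, 448), 10000)
  expect_equal(flux(600, 44800, 0.01, 3, 448), 10000)  # (200 - 100)/0.01
  expect_equal(flux(300, 44800, 0.01, 3, 448), 0)      # exact cancellation
  expect_error(flux(300, 0, 0, 3, 448), class = "fura_invalid_input")
})

test_that("flux variance: scaling cases and Monte-Carlo oracle", {
  expect_equal(flux_variance(0, 0, 0.01, 3, 448), 0)
  expect_equal(flux_variance(9, 0, 1, 3, 448), 1)
  # brute-force oracle: simulate counts under the Gaussian CCD model at the
  # reference geometry and compare the empirical flux variance with the
  # propagated one (the flux is linear, so agreement is exact up to MC error)
  set.seed(7)
  n <- 2e5
  v_roi <- adu_variance(1000, ref_ccd, 3)
  v_bg <- adu_variance(44800, ref_ccd, 448)
  a <- rnorm(n, 1000, sqrt(v_roi))
  b <- rnorm(n, 44800, sqrt(v_bg))
  emp <- var(flux(a, b, 0.01, 3, 448))
  thr <- flux_variance(v_roi, v_bg, 0.01, 3, 448)
  # sample variance of n draws has relative SD sqrt(2/(n-1)); allow 3 sigma
  expect_lt(abs(emp - thr) / thr, 3 * sqrt(2 / (n - 1)))
})

test_that("ratio variance: direct evaluation and Monte-Carlo oracle", {
  expect_equal(ratio_variance(1, 1, 0, 0), 0)
  expect_equal(ratio_variance(1, 1, 0.01, 0.01), 0.02)
  expect_error(ratio_variance(1, 0, 0.01, 0.01),
               class = "fura_degenerate_ratio")
  # small-CV Taylor assumption: brute force over Gaussian draws, CVs <= 2%
  set.seed(8)
  n <- 2e5
  f340 <- 24777; f380 <- 111930
  s340 <- 0.02 * f340; s380 <- 0.015 * f380
  emp <- var(rnorm(n, f340, s340) / rnorm(n, f380, s380))
  thr <- ratio_variance(f340, f380, s340^2, s380^2)
  expect_lt(abs(emp - thr) / thr, 0.05)
})

test_that("ratiometric transform hits its calibration landmarks", {
  expect_equal(ca_from_ratio(ref_cal$r_min, ref_cal), 0)
  # ratio halfway between r_min and r_max maps to k_eff by definition
  expect_equal(ca_from_ratio((ref_cal$r_min + ref_cal$r_max) / 2, ref_cal),
               ref_cal$k_eff)
  # frozen: ratio generated at 0.059 uM inverts back (r = 0.221364583...)
  expect_equal(ca_from_ratio(0.221364583333333, ref_cal), 0.059,
               tolerance = 1e-12)
  expect_error(ca_from_ratio(ref_cal$r_max, ref_cal),
               class = "fura_out_of_range")
  # negative estimates below r_min are passed through, not clamped
  expect_lt(ca_from_ratio(ref_cal$r_min - 0.01, ref_cal), 0)
})

test_that("delta-method calcium variance equals (dCa/dr)^2 var_r", {
  set.seed(9)
  for (i in 1:100) {
    r <- runif(1, ref_cal$r_min * 0.5, ref_cal$r_max - 0.05)
    vr <- runif(1, 0, 1e-3)
    ca <- ca_from_ratio(r, ref_cal)
    got <- ca_variance_delta(r, ca, vr, ref_cal)
    # finite-difference derivative of the transform as independent oracle
    h <- 1e-6
    dcadr <- (ca_from_ratio(r + h, ref_cal) - ca_from_ratio(r - h, ref_cal)) /
      (2 * h)
    expect_equal(got, dcadr^2 * vr, tolerance = 1e-6)
  }
  expect_equal(ca_variance_delta(0.5, ca_from_ratio(0.5, ref_cal), 0,
                                 ref_cal), 0)
})

test_that("Monte-Carlo SE: degenerate, reproducible, agrees with delta", {
  cc <- expected_counts_at(0.1)
  set.seed(5)
  a <- ca_se_monte_carlo(cc$adu340, cc$adu340_bg, cc$adu380, cc$adu380_bg,
                         ref$acquisition, k = 2e4)
  set.seed(5)
  b <- ca_se_monte_carlo(cc$adu340, cc$adu340_bg, cc$adu380, cc$adu380_bg,
                         ref$acquisition, k = 2e4)
  expect_identical(a$se_mc, b$se_mc)     # bit-identical under fixed seed
  expect_equal(a$offscale_fraction, 0)
  d <- delta_se_at(cc)
  expect_lt(abs(a$se_mc - d) / d, 3 * sqrt(1 / (2 * 2e4 - 2)) + 0.005)
  expect_error(ca_se_monte_carlo(1, 1, 1, 1, ref$acquisition, k = 1),
               class = "fura_invalid_input")
})

test_that("transient estimation round-trips noise-free expected counts", {
  g <- decay_grid(ref$decay, span = 10, by = 0.5)
  ex <- expected_transient(g, ref$decay, ref$illumination, ref$acquisition)
  est <- estimate_transient(ex$series, ref$acquisition, method = "delta")
  expect_true(all(est$valid))
  expect_equal(est$ca, ex$true_ca, tolerance = 1e-12)
  expect_true(all(est$se_delta > 0))
})

test_that("estimate_transient marks degenerate points invalid, keeps them", {
  s <- transient_series(time = c(0, 1, 2),
                        adu_340 = c(1700, 1700, 1700),
                        adu_340_bg = c(124000, 124000, 124000),
                        adu_380 = c(1700, 100, 1700),   # point 2: f380 < 0
                        adu_380_bg = c(139700, 139700, 139700))
  est <- estimate_transient(s, ref$acquisition, method = "delta")
  expect_equal(nrow(est), 3L)
  expect_equal(est$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(est$ca[2]))
  # single-point series works
  one <- transient_series(0, 1700, 124000, 1700, 139700)
  expect_equal(nrow(estimate_transient(one, ref$acquisition,
                                       method = "delta")), 1L)
})

test_that("estimator/simulator round trip on the calibration curve", {
  ca <- seq(0, 10 * ref_cal$k_eff, length.out = 50)
  expect_equal(ca_from_ratio(ratio_from_ca(ca, ref_cal), ref_cal), ca,
               tolerance = 1e-14)
})
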