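test_that("calcium time course: step, e-folding, asymptote", {
  dyn <- ref$decay
  expect_equal(ca_timecourse(dyn$t0, dyn), 0.059 + 0.114)
  expect_equal(ca_timecourse(dyn$t0 + dyn$tau, dyn), 0.059 + 0.114 / exp(1))
  expect_equal(ca_timecourse(dyn$t0 + 1e6, dyn), 0.059)
  expect_equal(ca_timecourse(dyn$t0 - 1, dyn), 0.059)  # pre-event baseline
})

test_that("intensity model: background level and algebraic consistency", {
  ii <- intensities(0.059, ref$illumination, ref$acquisition)
  expect_equal(ii$i340_bg, 849013.76)     # F340B * T340 * PB, frozen
  expect_true(all(unlist(ii) > 0))
  # background-corrected per-pixel rate ratio equals the calibration curve,
  # so the ratiometric transform inverts the forward model exactly
  acq <- ref$acquisition
  ca <- c(0, 0.059, 0.173, 1.2, 9)
  ii <- intensities(ca, ref$illumination, acq)
  num <- ii$i340 / (acq$p_roi * acq$t_340) - ref$illumination$f340_bg
  den <- ii$i380 / (acq$p_roi * acq$t_380) - ref$illumination$f380_bg
  expect_equal(num / den, ratio_from_ca(ca, ref_cal), tolerance = 1e-12)
  expect_equal((num / den)[1], ref_cal$r_min)   # zero-calcium limit
  expect_error(intensities(-0.1, ref$illumination, acq),
               class = "fura_invalid_input")
})

test_that("ratio_from_ca: limits and midpoint", {
  expect_equal(ratio_from_ca(0, ref_cal), 0.147)
  expect_equal(ratio_from_ca(ref_cal$k_eff, ref_cal), (0.147 + 1.599) / 2)
  expect_equal(ratio_from_ca(1e9, ref_cal), ref_cal$r_max, tolerance = 1e-6)
})

test_that("sampled counts match the Gaussian CCD moments", {
  set.seed(11)
  ccd <- ref_ccd
  intensity <- 1.1e4
  n <- 1e5
  draws <- sample_adu(intensity, ccd, 3, n = n)
  mu <- ccd$gain * intensity
  s2 <- ccd$gain^2 * intensity + ccd$gain^2 * 3 * ccd$readout_variance
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(s2 / n))
  expect_lt(abs(var(draws) - s2), 4 * s2 * sqrt(2 / (n - 1)))
  # degenerate: no photons, no read-out noise -> exactly zero
  expect_equal(sample_adu(0, ccd_params(1, 0), 1), 0)
})

test_that("simulated transients are reproducible and well-formed", {
  a <- quick_sim(seed = 3)
  b <- quick_sim(seed = 3)
  expect_identical(a, b)
  expect_s3_class(a$series, "fura_transient")
  expect_equal(length(a$true_ca), nrow(a$series))
  expect_error(simulate_transient(numeric(0), ref$decay, ref$illumination,
                                  ref$acquisition), class = "fura_invalid_input")
})

test_that("340 signal rises and 380 falls with calcium", {
  ca <- seq(0, 2, length.out = 30)
  ii <- intensities(ca, ref$illumination, ref$acquisition)
  expect_true(all(diff(ii$i340) > 0))
  expect_true(all(diff(ii$i380) < 0))
})

test_that("dye-free control: ROI flux equals background flux in expectation", {
  illum0 <- illumination_model(0, ref$illumination$f340_bg,
                               ref$illumination$f380_bg)
  g <- decay_grid(ref$decay, span = 2, by = 0.5)
  ex <- expected_transient(g, ref$decay, illum0, ref$acquisition)
  acq <- ref$acquisition
  f340 <- flux(ex$series$adu340, ex$series$adu340_bg, acq$t_340,
               acq$p_roi, acq$p_bg)
  f380 <- flux(ex$series$adu380, ex$series$adu380_bg, acq$t_380,
               acq$p_roi, acq$p_bg)
  expect_equal(f340, rep(0, length(g)), tolerance = 1e-9)
  expect_equal(f380, rep(0, length(g)), tolerance = 1e-9)
})
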