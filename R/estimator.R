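#' Background-corrected fluorescence flux
#'
#' Converts raw ROI and background counts into a fluorescence intensity per
#' pixel per second,
#' \deqn{f_\lambda = \frac{1}{T_\lambda}\left(\frac{adu_\lambda}{P} -
#'   \frac{adu_{\lambda,B}}{P_B}\right),}
#' assuming uniform autofluorescence across ROI and background region.  The
#' result may be negative when noise pushes the ROI below the background.
#'
#' @param adu,adu_bg ROI and background counts (ADU). Vectorized.
#' @param exposure exposure time \eqn{T_\lambda} (s), positive.
#' @param p_roi,p_bg pixel counts of the ROI and the background region.
#' @return flux in ADU per pixel per second.
#' @export
flux <- function(adu, adu_bg, exposure, p_roi, p_bg) {
  exposure <- check_scalar(exposure, "exposure", 0, strict = TRUE)
  p_roi <- check_scalar(p_roi, "p_roi", 1, integerish = TRUE)
  p_bg <- check_scalar(p_bg, "p_bg", 1, integerish = TRUE)
  (adu / p_roi - adu_bg / p_bg) / exposure
}

#' First-order variance of the background-corrected flux
#'
#' Propagates the plug-in count variances through [flux()]:
#' \deqn{\hat\sigma^2_{f_\lambda} = \frac{1}{T_\lambda^2}\left(
#'   \frac{\hat\sigma^2_{ADU_\lambda}}{P^2} +
#'   \frac{\hat\sigma^2_{ADU_{\lambda,B}}}{P_B^2}\right).}
#' Exact (not merely first order) because [flux()] is linear in the counts.
#'
#' @param adu_var,adu_bg_var count variances (ADU^2) from [adu_variance()].
#'   Vectorized.
#' @inheritParams flux
#' @return flux variance in (ADU/pixel/s)^2.
#' @export
flux_variance <- function(adu_var, adu_bg_var, exposure, p_roi, p_bg) {
  exposure <- check_scalar(exposure, "exposure", 0, strict = TRUE)
  p_roi <- check_scalar(p_roi, "p_roi", 1, integerish = TRUE)
  p_bg <- check_scalar(p_bg, "p_bg", 1, integerish = TRUE)
  if (any(adu_var < 0) || any(adu_bg_var < 0))
    stop_invalid("variances must be non-negative")
  (adu_var / p_roi^2 + adu_bg_var / p_bg^2) / exposure^2
}

#' First-order variance of the fluorescence ratio
#'
#' Delta-method variance of \eqn{r = f_{340}/f_{380}}:
#' \deqn{\hat\sigma^2_r = \frac{1}{f_{380}^2}\left(\hat\sigma^2_{f_{340}} +
#'   r^2 \hat\sigma^2_{f_{380}}\right).}
#' Valid when the coefficients of variation of both fluxes are small (a few
#' percent), which holds at usual signal levels.
#'
#' @param f340,f380 background-corrected fluxes; `f380` must be nonzero.
#'   Vectorized.
#' @param var340,var380 flux variances from [flux_variance()].
#' @return variance of the ratio (dimensionless).
#' @export
ratio_variance <- function(f340, f380, var340, var380) {
  if (any(f380 == 0))
    stop(errorCondition("f380 is zero: ratio undefined at this point",
                        class = c("fura_degenerate_ratio", "error")))
  if (any(var340 < 0) || any(var380 < 0))
    stop_invalid("variances must be non-negative")
  r <- f340 / f380
  (var340 + r^2 * var380) / f380^2
}

#' Ratiometric calcium estimator
#'
#' The classical two-wavelength transform
#' \deqn{\widehat{Ca} = K_{eff}\,\frac{r - R_{min}}{R_{max} - r},}
#' zero at ratio `r_min`, diverging as the ratio approaches `r_max`.  Ratios
#' slightly below `r_min` (possible through noise at very low calcium) give
#' negative estimates which are returned as-is — clamping them to zero would
#' bias downstream weighted fits.
#'
#' @param r fluorescence ratio(s); must be `< r_max`. Vectorized.
#' @param cal a [calibration_params()] object.
#' @return estimated free-calcium concentration(s), uM.
#' @export
#' @examples
#' cal <- calibration_params(0.147, 1.599, 1.093, 0.225)
#' ca_from_ratio((0.147 + 1.599) / 2, cal)  # equals k_eff
ca_from_ratio <- function(r, cal) {
  if (!inherits(cal, "calibration_params"))
    stop_invalid("cal must be a calibration_params object")
  if (any(!is.finite(r))) stop_invalid("r must be finite")
  if (any(r >= cal$r_max))
    stop(errorCondition(
      "ratio at or above r_max: estimator out of range",
      class = c("fura_out_of_range", "error")))
  cal$k_eff * (r - cal$r_min) / (cal$r_max - r)
}

#' Delta-method variance of the calcium estimate
#'
#' First-order propagation of the ratio variance through [ca_from_ratio()].
#' The exact derivative of the transform is
#' \deqn{\frac{d\,Ca}{d\,r} = \frac{K_{eff}(R_{max}-R_{min})}{(R_{max}-r)^2}
#'   = \frac{K_{eff}}{R_{max}-r}\left(1 + \frac{\widehat{Ca}}{K_{eff}}\right),}
#' so
#' \deqn{\hat\sigma^2_{Ca} = \left(\frac{K_{eff}}{R_{max}-r}\right)^2
#'   \left(1 + \widehat{Ca}/K_{eff}\right)^2 \hat\sigma^2_r.}
#' (The second factor is the dimensionless calcium in units of
#' \eqn{K_{eff}}; writing it that way keeps the expression dimensionally
#' consistent.)
#'
#' @param r fluorescence ratio(s), `< r_max`. Vectorized.
#' @param ca calcium estimate(s) from [ca_from_ratio()] (uM).
#' @param var_r ratio variance(s) from [ratio_variance()].
#' @param cal a [calibration_params()] object.
#' @return variance of the calcium estimate, uM^2.
#' @export
ca_variance_delta <- function(r, ca, var_r, cal) {
  if (!inherits(cal, "calibration_params"))
    stop_invalid("cal must be a calibration_params object")
  if (any(r >= cal$r_max))
    stop(errorCondition("ratio at or above r_max",
                        class = c("fura_out_of_range", "error")))
  if (any(var_r < 0)) stop_invalid("var_r must be non-negative")
  (cal$k_eff / (cal$r_max - r))^2 * (1 + ca / cal$k_eff)^2 * var_r
}

#' Monte-Carlo standard error of the calcium estimate at one time point
#'
#' Draws `k` independent count quadruples
#' \eqn{adu_\lambda[j] = adu_\lambda + z_\lambda[j]\,\hat\sigma_{ADU_\lambda}}
#' (four independent Gaussian streams, drawn in the documented order
#' 340-ROI, 340-background, 380-ROI, 380-background), maps each through the
#' flux, ratio and calcium transforms, and returns the square root of the
#' unbiased sample variance of the `k` calcium values.
#'
#' Draws falling off the estimator's scale — ratio at/above `r_max` or
#' `f380 <= 0` —
#' are excluded and their fraction reported, since a single near-divergent
#' draw would dominate the sample variance.  If that fraction exceeds 1% a
#' warning suggests inspecting the histogram of the Monte-Carlo calcium
#' values: the delta method is unreliable there too, and the discrepancy
#' between the two methods flags genuine non-normality.
#'
#' @param adu_340,adu_340_bg,adu_380,adu_380_bg observed counts (ADU) at one
#'   time point.
#' @param params an [acquisition_params()] object.
#' @param k number of Monte-Carlo draws (default 10^4).
#' @return a list with elements `se_mc` (uM), `offscale_fraction`, `k_used`
#'   (draws retained), and `ca_mean` (mean of retained draws, uM).
#' @export
ca_se_monte_carlo <- function(adu_340, adu_340_bg, adu_380, adu_380_bg,
                              params, k = 10000L) {
  if (!inherits(params, "acquisition_params"))
    stop_invalid("params must be an acquisition_params object")
  k <- check_scalar(k, "k", 2, integerish = TRUE)
  cal <- params$calibration
  sd4 <- sqrt(c(
    adu_variance(adu_340, params$ccd, params$p_roi),
    adu_variance(adu_340_bg, params$ccd, params$p_bg),
    adu_variance(adu_380, params$ccd, params$p_roi),
    adu_variance(adu_380_bg, params$ccd, params$p_bg)))
  # draw order is part of the reproducibility contract
  a340 <- adu_340 + rnorm(k) * sd4[1L]
  a340b <- adu_340_bg + rnorm(k) * sd4[2L]
  a380 <- adu_380 + rnorm(k) * sd4[3L]
  a380b <- adu_380_bg + rnorm(k) * sd4[4L]
  f340 <- flux(a340, a340b, params$t_340, params$p_roi, params$p_bg)
  f380 <- flux(a380, a380b, params$t_380, params$p_roi, params$p_bg)
  r <- f340 / f380
  ok <- f380 > 0 & r < cal$r_max
  n_ok <- sum(ok)
  if (n_ok < 2L)
    stop(errorCondition(
      "Monte-Carlo standard error unavailable: all draws off-scale",
      class = c("fura_estimation_failure", "error")))
  off <- 1 - n_ok / k
  if (off > 0.01)
    warning(sprintf(
      paste0("%.1f%% of Monte-Carlo draws off-scale; the estimator ",
             "distribution is likely non-normal here - inspect the ",
             "histogram of the Monte-Carlo calcium draws"), 100 * off))
  ca <- cal$k_eff * (r[ok] - cal$r_min) / (cal$r_max - r[ok])
  list(se_mc = stats::sd(ca), offscale_fraction = off,
       k_used = n_ok, ca_mean = mean(ca))
}

delta_point <- function(adu_340, adu_340_bg, adu_380, adu_380_bg, params) {
  cal <- params$calibration
  f340 <- flux(adu_340, adu_340_bg, params$t_340, params$p_roi, params$p_bg)
  f380 <- flux(adu_380, adu_380_bg, params$t_380, params$p_roi, params$p_bg)
  if (f380 <= 0)
    return(list(f340 = f340, f380 = f380, ratio = NA_real_, ca = NA_real_,
                se = NA_real_, valid = FALSE))
  r <- f340 / f380
  if (r >= cal$r_max)
    return(list(f340 = f340, f380 = f380, ratio = r, ca = NA_real_,
                se = NA_real_, valid = FALSE))
  v340 <- flux_variance(adu_variance(adu_340, params$ccd, params$p_roi),
                        adu_variance(adu_340_bg, params$ccd, params$p_bg),
                        params$t_340, params$p_roi, params$p_bg)
  v380 <- flux_variance(adu_variance(adu_380, params$ccd, params$p_roi),
                        adu_variance(adu_380_bg, params$ccd, params$p_bg),
                        params$t_380, params$p_roi, params$p_bg)
  vr <- ratio_variance(f340, f380, v340, v380)
  ca <- ca_from_ratio(r, cal)
  list(f340 = f340, f380 = f380, ratio = r, ca = ca,
       se = sqrt(ca_variance_delta(r, ca, vr, cal)), valid = TRUE)
}

#' Estimate a calcium transient with standard errors
#'
#' Applies the ratiometric estimator and its standard error(s) to every time
#' point of a [transient_series()].  Time points where the estimator is
#' undefined (`f380 <= 0` or ratio at/above `r_max`) are kept in the output
#' with `valid = FALSE` and `NA` estimates — never silently dropped.
#'
#' @param series a [transient_series()].
#' @param params an [acquisition_params()] object.
#' @param method `"both"` (default), `"delta"` or `"mc"`: which standard
#'   error(s) to compute.
#' @param k Monte-Carlo draws per time point (default 10^4).
#' @param seed optional integer; when supplied the Monte-Carlo stream is
#'   seeded once before the (time-ordered) per-point draws, making the run
#'   bit-reproducible.
#' @return a data frame of class `fura_estimates` with columns `time`,
#'   `f340`, `f380`, `ratio`, `ca`, `se_delta`, `se_mc`,
#'   `mc_offscale_fraction`, `valid`.
#' @export
#' @examples
#' p <- fura_default_params()
#' sim <- simulate_transient(decay_grid(p$decay, span = 3, by = 0.5),
#'                           p$decay, p$illumination, p$acquisition, seed = 7)
#' estimate_transient(sim$series, p$acquisition, method = "delta")
estimate_transient <- function(series, params,
                               method = c("both", "delta", "mc"),
                               k = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (!inherits(series, "fura_transient"))
    series <- transient_series(series$time, series$adu340, series$adu340_bg,
                               series$adu380, series$adu380_bg)
  if (!inherits(params, "acquisition_params"))
    stop_invalid("params must be an acquisition_params object")
  n <- nrow(series)
  if (n == 0L) stop_invalid("empty series")
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- data.frame(
    time = series$time, f340 = NA_real_, f380 = NA_real_, ratio = NA_real_,
    ca = NA_real_, se_delta = NA_real_, se_mc = NA_real_,
    mc_offscale_fraction = NA_real_, valid = FALSE)
  for (i in seq_len(n)) {
    d <- delta_point(series$adu340[i], series$adu340_bg[i],
                     series$adu380[i], series$adu380_bg[i], params)
    out$f340[i] <- d$f340; out$f380[i] <- d$f380; out$ratio[i] <- d$ratio
    out$ca[i] <- d$ca; out$valid[i] <- d$valid
    if (method %in% c("both", "delta")) out$se_delta[i] <- d$se
    if (method %in% c("both", "mc") && d$valid) {
      mc <- ca_se_monte_carlo(series$adu340[i], series$adu340_bg[i],
                              series$adu380[i], series$adu380_bg[i],
                              params, k = k)
      out$se_mc[i] <- mc$se_mc
      out$mc_offscale_fraction[i] <- mc$offscale_fraction
    }
  }
  structure(out, class = c("fura_estimates", "data.frame"),
            method = method, k = as.integer(k), seed = seed)
}

#' @export
print.fura_estimates <- function(x, ...) {
  cat(sprintf(
    "Ratiometric calcium estimates: %d points (%d valid), method '%s'\n",
    nrow(x), sum(x$valid), attr(x, "method")))
  NextMethod()
}
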