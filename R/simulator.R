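#' Monoexponential calcium time course
#'
#' \eqn{Ca(t) = Ca_0} for `t < t0` and
#' \eqn{Ca_0 + \delta e^{-(t-t_0)/\tau}} for `t >= t0`: a step of amplitude
#' `delta` at `t0` relaxing back to baseline, mimicking the tail of a
#' depolarization-evoked calcium transient.
#'
#' @param t times (s), finite; any order.
#' @param dyn a [decay_params()] object.
#' @return free-calcium concentrations (uM), same length as `t`.
#' @export
ca_timecourse <- function(t, dyn) {
  if (!inherits(dyn, "decay_params"))
    stop_invalid("dyn must be a decay_params object")
  if (any(!is.finite(t))) stop_invalid("t must be finite")
  ifelse(t < dyn$t0, dyn$ca0,
         dyn$ca0 + dyn$delta * exp(-(t - dyn$t0) / dyn$tau))
}

#' Regular sampling grid over the decay phase
#'
#' Convenience constructor for the default simulation grid: regular
#' sampling from the event time `t0` over `span` seconds.  The default 30 s
#' window at 0.15 s spacing (201 points) covers more than 10 decay time
#' constants of the packaged kinetics.
#'
#' @param dyn a [decay_params()] object (supplies `t0`).
#' @param span window length (s) past `t0`.
#' @param by sampling interval (s).
#' @return numeric vector of times (s).
#' @export
decay_grid <- function(dyn, span = 30, by = 0.15) {
  if (!inherits(dyn, "decay_params"))
    stop_invalid("dyn must be a decay_params object")
  span <- check_scalar(span, "span", 0, strict = TRUE)
  by <- check_scalar(by, "by", 0, strict = TRUE)
  seq(dyn$t0, dyn$t0 + span, by = by)
}

#' Expected photo-electron counts at a given calcium concentration
#'
#' The forward intensity model. With total-dye photon rate
#' \eqn{[Fura]_{tot}\phi}, dissociation constant \eqn{K_{Fura}} and
#' autofluorescence rates \eqn{F_{\lambda B}}:
#' \deqn{I_{340} = \left\{\frac{[Fura]_{tot}\phi}{K_{Fura}+Ca}
#'   (R_{min}K_{eff} + R_{max} Ca) + F_{340B}\right\} T_{340} P}
#' \deqn{I_{380} = \left\{\frac{[Fura]_{tot}\phi}{K_{Fura}+Ca}
#'   (K_{eff} + Ca) + F_{380B}\right\} T_{380} P}
#' and background intensities \eqn{I_{\lambda B} = F_{\lambda B} T_\lambda
#' P_B}.  The background-corrected per-pixel rate ratio of the two dye terms
#' is exactly the ratio inverted by [ca_from_ratio()]; as calcium rises the
#' 340 nm signal increases while the 380 nm signal decreases.
#'
#' @param ca free-calcium concentration(s), uM, non-negative. Vectorized.
#' @param illum an [illumination_model()] object.
#' @param params an [acquisition_params()] object.
#' @return a list with vectors `i340`, `i340_bg`, `i380`, `i380_bg`
#'   (photo-electrons collected during the respective exposures).
#' @export
intensities <- function(ca, illum, params) {
  if (!inherits(illum, "illumination_model"))
    stop_invalid("illum must be an illumination_model object")
  if (!inherits(params, "acquisition_params"))
    stop_invalid("params must be an acquisition_params object")
  if (any(!is.finite(ca)) || any(ca < 0))
    stop_invalid("ca must be finite and non-negative")
  cal <- params$calibration
  dye <- illum$fura_total_phi / (cal$k_fura + ca)
  list(
    i340 = (dye * (cal$r_min * cal$k_eff + cal$r_max * ca) + illum$f340_bg) *
      params$t_340 * params$p_roi,
    i340_bg = rep_len(illum$f340_bg * params$t_340 * params$p_bg, length(ca)),
    i380 = (dye * (cal$k_eff + ca) + illum$f380_bg) *
      params$t_380 * params$p_roi,
    i380_bg = rep_len(illum$f380_bg * params$t_380 * params$p_bg, length(ca))
  )
}

#' Noise-free fluorescence ratio at a given calcium concentration
#'
#' The inverse of [ca_from_ratio()]:
#' \deqn{r(Ca) = \frac{R_{min} K_{eff} + R_{max} Ca}{K_{eff} + Ca},}
#' rising from \eqn{R_{min}} at zero calcium towards \eqn{R_{max}} at
#' saturation, passing through the midpoint at \eqn{Ca = K_{eff}}.
#'
#' @param ca free-calcium concentration(s), uM, non-negative. Vectorized.
#' @param cal a [calibration_params()] object.
#' @return dimensionless ratio(s) in `[r_min, r_max)`.
#' @export
ratio_from_ca <- function(ca, cal) {
  if (!inherits(cal, "calibration_params"))
    stop_invalid("cal must be a calibration_params object")
  if (any(!is.finite(ca)) || any(ca < 0))
    stop_invalid("ca must be finite and non-negative")
  (cal$r_min * cal$k_eff + cal$r_max * ca) / (cal$k_eff + ca)
}

#' Draw a CCD count for a given expected photo-electron intensity
#'
#' One Gaussian draw per intensity with mean \eqn{G I} and variance
#' \eqn{G^2 I + G^2 P \sigma^2_{ro}} (shot noise plus read-out noise, both
#' expressed in ADU^2).  Counts are kept as real numbers — no quantization —
#' consistent with the Gaussian measurement model; rare negative draws at
#' very low intensity are passed through unchanged.
#'
#' @param intensity expected photo-electron count(s), non-negative.
#' @param ccd a [ccd_params()] object.
#' @param n_pixels pixels contributing read-out noise (region size).
#' @param n draws per intensity value (default 1; used by moment checks).
#' @return simulated ADU count(s); a vector of length `length(intensity)`
#'   when `n = 1`, else an `n x length(intensity)` matrix.
#' @export
sample_adu <- function(intensity, ccd, n_pixels, n = 1L) {
  if (!inherits(ccd, "ccd_params"))
    stop_invalid("ccd must be a ccd_params object")
  n_pixels <- check_scalar(n_pixels, "n_pixels", 1, integerish = TRUE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_invalid("intensity must be finite and non-negative")
  mu <- ccd$gain * intensity
  sdv <- sqrt(ccd$gain^2 * intensity +
                ccd$gain^2 * n_pixels * ccd$readout_variance)
  if (n == 1L) return(rnorm(length(intensity), mu, sdv))
  matrix(rnorm(n * length(intensity), rep(mu, each = n), rep(sdv, each = n)),
         nrow = n)
}

#' Simulate a two-wavelength transient from a known calcium time course
#'
#' Computes the calcium time course, the four expected intensities at each
#' time point, and draws independent Gaussian counts for every (time point,
#' channel) pair — channel order 340-ROI, 340-background, 380-ROI,
#' 380-background within each time point.
#'
#' @param times sampling times (s), strictly increasing; see [decay_grid()].
#' @param dyn a [decay_params()] object.
#' @param illum an [illumination_model()] object.
#' @param params an [acquisition_params()] object.
#' @param seed optional integer for bit-reproducible output.
#' @return a list with `series` (a [transient_series()]) and `true_ca` (the
#'   ground-truth calcium vector, uM).
#' @export
#' @examples
#' p <- fura_default_params()
#' sim <- simulate_transient(decay_grid(p$decay, span = 2, by = 0.5),
#'                           p$decay, p$illumination, p$acquisition, seed = 1)
#' sim$series
simulate_transient <- function(times, dyn, illum, params, seed = NULL) {
  if (length(times) < 1L) stop_invalid("empty times")
  if (any(!is.finite(times))) stop_invalid("times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing")
  true_ca <- ca_timecourse(times, dyn)
  ii <- intensities(true_ca, illum, params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(times)
  a340 <- a340b <- a380 <- a380b <- numeric(n)
  for (i in seq_len(n)) {
    a340[i] <- sample_adu(ii$i340[i], params$ccd, params$p_roi)
    a340b[i] <- sample_adu(ii$i340_bg[i], params$ccd, params$p_bg)
    a380[i] <- sample_adu(ii$i380[i], params$ccd, params$p_roi)
    a380b[i] <- sample_adu(ii$i380_bg[i], params$ccd, params$p_bg)
  }
  # intensities here are large enough that negative draws are (much) rarer
  # than 1e-300; clamp defensively so transient_series invariants hold
  list(series = transient_series(times, pmax(a340, 0), pmax(a340b, 0),
                                 pmax(a380, 0), pmax(a380b, 0)),
       true_ca = true_ca)
}

#' Expected (noise-free) counts for a calcium time course
#'
#' Returns the transient the camera would record in the absence of any
#' noise: counts equal to gain times expected intensity.  Used by the
#' round-trip and monotonicity checks and available for power analyses.
#'
#' @inheritParams simulate_transient
#' @return a list with `series` and `true_ca`, as [simulate_transient()].
#' @export
expected_transient <- function(times, dyn, illum, params) {
  if (length(times) < 1L) stop_invalid("empty times")
  true_ca <- ca_timecourse(times, dyn)
  ii <- intensities(true_ca, illum, params)
  g <- params$ccd$gain
  list(series = transient_series(times, g * ii$i340, g * ii$i340_bg,
                                 g * ii$i380, g * ii$i380_bg),
       true_ca = true_ca)
}
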