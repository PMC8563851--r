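#' Parameter containers for ratiometric calcium estimation
#'
#' Lightweight validated lists holding, respectively: the CCD noise
#' parameters, the ratiometric calibration constants, the full static
#' acquisition description (geometry, exposures, CCD, calibration), the
#' illumination/autofluorescence model used by the forward simulator, and
#' the monoexponential calcium decay parameters.
#'
#' @name fura-params
NULL

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fura_invalid_input", "error")))
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict && x <= lower)
    stop_invalid(name, " must be > ", lower, " (got ", x, ")")
  if (!strict && x < lower)
    stop_invalid(name, " must be >= ", lower, " (got ", x, ")")
  if (integerish && x != round(x))
    stop_invalid(name, " must be a whole number (got ", x, ")")
  as.numeric(x)
}

#' @rdname fura-params
#' @param gain CCD gain G, ADU per photo-electron. Must be positive.
#' @param readout_variance read-out variance \eqn{\sigma^2_{ro}},
#'   photo-electrons squared per pixel. Must be non-negative.
#' @return `ccd_params()`: an object of class `ccd_params`.
#' @export
#' @examples
#' ccd_params(gain = 0.146, readout_variance = 268.96)
ccd_params <- function(gain, readout_variance) {
  structure(list(
    gain = check_scalar(gain, "gain", 0, strict = TRUE),
    readout_variance = check_scalar(readout_variance, "readout_variance", 0)
  ), class = "ccd_params")
}

#' @rdname fura-params
#' @param r_min,r_max calibrated fluorescence ratios at zero and at
#'   saturating calcium (dimensionless, `0 < r_min < r_max`).
#' @param k_eff effective dissociation constant \eqn{K_{eff}} (uM): the
#'   calcium concentration at which the ratio sits halfway between `r_min`
#'   and `r_max`.
#' @param k_fura Fura-2 dissociation constant \eqn{K_{Fura}} (uM), used by
#'   the intensity model of the simulator.
#' @return `calibration_params()`: an object of class `calibration_params`.
#' @export
calibration_params <- function(r_min, r_max, k_eff, k_fura) {
  r_min <- check_scalar(r_min, "r_min", 0, strict = TRUE)
  r_max <- check_scalar(r_max, "r_max", 0, strict = TRUE)
  if (r_min >= r_max)
    stop_invalid("r_min (", r_min, ") must be < r_max (", r_max, ")")
  structure(list(
    r_min = r_min, r_max = r_max,
    k_eff = check_scalar(k_eff, "k_eff", 0, strict = TRUE),
    k_fura = check_scalar(k_fura, "k_fura", 0, strict = TRUE)
  ), class = "calibration_params")
}

#' @rdname fura-params
#' @param calibration a [calibration_params()] object.
#' @param ccd a [ccd_params()] object.
#' @param p_roi number of CCD pixels in the region of interest (ROI).
#' @param p_bg number of CCD pixels in the background measurement region.
#' @param t_340,t_380 exposure times (s) at 340 and 380 nm excitation.
#' @return `acquisition_params()`: an object of class `acquisition_params`.
#' @export
acquisition_params <- function(calibration, ccd, p_roi, p_bg, t_340, t_380) {
  if (!inherits(calibration, "calibration_params"))
    stop_invalid("calibration must be a calibration_params object")
  if (!inherits(ccd, "ccd_params"))
    stop_invalid("ccd must be a ccd_params object")
  structure(list(
    calibration = calibration, ccd = ccd,
    p_roi = check_scalar(p_roi, "p_roi", 1, integerish = TRUE),
    p_bg = check_scalar(p_bg, "p_bg", 1, integerish = TRUE),
    t_340 = check_scalar(t_340, "t_340", 0, strict = TRUE),
    t_380 = check_scalar(t_380, "t_380", 0, strict = TRUE)
  ), class = "acquisition_params")
}

#' @rdname fura-params
#' @param fura_total_phi product of total Fura concentration and the
#'   experiment-specific photon-collection factor \eqn{[Fura]_{tot}\phi}
#'   (1/s).
#' @param f340_bg,f380_bg autofluorescence rates per pixel per second at
#'   340 and 380 nm.
#' @return `illumination_model()`: an object of class `illumination_model`.
#' @export
illumination_model <- function(fura_total_phi, f340_bg, f380_bg) {
  structure(list(
    fura_total_phi = check_scalar(fura_total_phi, "fura_total_phi", 0),
    f340_bg = check_scalar(f340_bg, "f340_bg", 0),
    f380_bg = check_scalar(f380_bg, "f380_bg", 0)
  ), class = "illumination_model")
}

#' @rdname fura-params
#' @param t0 event time (s): calcium jumps at `t0` then decays.
#' @param ca0 baseline free-calcium concentration (uM).
#' @param delta jump amplitude (uM) at `t0`.
#' @param tau decay time constant (s).
#' @return `decay_params()`: an object of class `decay_params`.
#' @export
decay_params <- function(t0, ca0, delta, tau) {
  structure(list(
    t0 = check_scalar(t0, "t0"),
    ca0 = check_scalar(ca0, "ca0", 0),
    delta = check_scalar(delta, "delta", 0),
    tau = check_scalar(tau, "tau", 0, strict = TRUE)
  ), class = "decay_params")
}

# Reference values for a perforated-patch Fura-2 recording (CCD with 3-pixel
# ROI and 448-pixel background region); these are the packaged defaults used
# by the simulator, the CLI and the validation pipeline.
FURA_DEFAULTS <- list(
  r_min = 0.147, r_max = 1.599, k_eff = 1.093, k_fura = 0.225,
  fura_total_phi = 1.89e5,
  t_340 = 0.01, t_380 = 0.003, p_roi = 3, p_bg = 448,
  gain = 0.146, readout_variance = 268.96,
  f340_bg = 189512, f380_bg = 711589,
  t0 = 2283.415, ca0 = 0.059, delta = 0.114, tau = 2.339
)

#' Packaged default parameter set
#'
#' Returns the default acquisition, illumination and decay parameters: the
#' calibrated constants of a reference Fura-2 recording from a
#' perforated-patch experiment (3-pixel ROI, 448-pixel background region,
#' 10/3 ms exposures) and the monoexponential tail of its first calcium
#' transient. These drive the simulator and validation defaults.
#'
#' @return a list with elements `acquisition` ([acquisition_params()]),
#'   `illumination` ([illumination_model()]) and `decay` ([decay_params()]).
#' @export
#' @examples
#' p <- fura_default_params()
#' p$acquisition$calibration$k_eff
fura_default_params <- function() {
  d <- FURA_DEFAULTS
  list(
    acquisition = acquisition_params(
      calibration = calibration_params(d$r_min, d$r_max, d$k_eff, d$k_fura),
      ccd = ccd_params(d$gain, d$readout_variance),
      p_roi = d$p_roi, p_bg = d$p_bg, t_340 = d$t_340, t_380 = d$t_380
    ),
    illumination = illumination_model(d$fura_total_phi, d$f340_bg, d$f380_bg),
    decay = decay_params(d$t0, d$ca0, d$delta, d$tau)
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cal <- x$calibration
  cat("Acquisition parameters\n")
  cat(sprintf("  ROI: %d px   background: %d px   T340: %g s   T380: %g s\n",
              as.integer(x$p_roi), as.integer(x$p_bg), x$t_340, x$t_380))
  cat(sprintf("  CCD: gain %g ADU/e-, read-out variance %g e-^2/px\n",
              x$ccd$gain, x$ccd$readout_variance))
  cat(sprintf("  Calibration: Rmin %g, Rmax %g, Keff %g uM, KFura %g uM\n",
              cal$r_min, cal$r_max, cal$k_eff, cal$k_fura))
  invisible(x)
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf(
    "Monoexponential decay: Ca(t) = %g + %g exp(-(t - %g)/%g) uM for t >= t0\n",
    x$ca0, x$delta, x$t0, x$tau))
  invisible(x)
}
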