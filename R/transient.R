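#' Two-wavelength ROI/background count time series
#'
#' Bundles, per time point, the four raw camera counts needed by the
#' ratiometric method: ROI and background counts under 340 nm and 380 nm
#' excitation.  Stored as a data frame with class `fura_transient`.
#'
#' @param time acquisition times (s), strictly increasing.
#' @param adu_340,adu_340_bg,adu_380,adu_380_bg raw counts (ADU) in the ROI
#'   and the background measurement region at each wavelength; finite,
#'   non-negative, same length as `time`.
#' @return a data frame of class `fura_transient` with columns `time`,
#'   `adu340`, `adu340_bg`, `adu380`, `adu380_bg`.
#' @export
#' @examples
#' transient_series(time = c(0, 0.15), adu_340 = c(1500, 1490),
#'                  adu_340_bg = c(123900, 124100),
#'                  adu_380 = c(1950, 1960),
#'                  adu_380_bg = c(312000, 311800))
transient_series <- function(time, adu_340, adu_340_bg, adu_380, adu_380_bg) {
  cols <- list(time = time, adu340 = adu_340, adu340_bg = adu_340_bg,
               adu380 = adu_380, adu380_bg = adu_380_bg)
  n <- length(time)
  if (n < 1L) stop_invalid("empty series")
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (!is.numeric(v) || length(v) != n)
      stop_invalid("column ", nm, " must be numeric of length ", n)
    if (any(!is.finite(v))) stop_invalid("non-finite value in ", nm)
  }
  if (n > 1L && any(diff(time) <= 0))
    stop_invalid("time must be strictly increasing")
  for (nm in names(cols)[-1L]) {
    if (any(cols[[nm]] < 0)) stop_invalid("negative count in ", nm)
  }
  structure(as.data.frame(cols), class = c("fura_transient", "data.frame"))
}

#' @export
print.fura_transient <- function(x, ...) {
  cat(sprintf("Fura-2 transient: %d time points, t in [%g, %g] s\n",
              nrow(x), x$time[1L], x$time[nrow(x)]))
  NextMethod()
}
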