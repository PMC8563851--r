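#' Plug-in variance of an observed CCD count
#'
#' A count recorded by a CCD with gain \eqn{G} (ADU per photo-electron) and
#' per-pixel read-out variance \eqn{\sigma^2_{ro}} over `n_pixels` pixels is
#' modelled as Gaussian with mean \eqn{\mu = G I} (\eqn{I} the collected
#' photo-electrons) and variance \eqn{G \mu + G^2 P \sigma^2_{ro}}.  Since
#' \eqn{\mu} is unknown, the observed count is plugged in for it, giving the
#' estimate
#' \deqn{\hat\sigma^2_{ADU} = G \, adu + G^2 P \sigma^2_{ro}.}
#' Individual points are thereby slightly over- or under-estimated, but the
#' errors average out over a transient (the estimate is unbiased because the
#' true variance is affine in the mean).
#'
#' @param adu observed count(s), ADU; must be finite and non-negative
#'   (negative counts indicate invalid preprocessing and are rejected rather
#'   than clamped, since the model is meaningless there). Vectorized.
#' @param ccd a [ccd_params()] object.
#' @param n_pixels number of pixels summed into the count (ROI or
#'   background region size).
#' @return estimated variance(s) in ADU^2; strictly positive whenever
#'   `readout_variance > 0`.
#' @export
#' @examples
#' ccd <- ccd_params(gain = 0.146, readout_variance = 268.96)
#' adu_variance(1000, ccd, n_pixels = 3)
adu_variance <- function(adu, ccd, n_pixels) {
  if (!inherits(ccd, "ccd_params"))
    stop_invalid("ccd must be a ccd_params object")
  n_pixels <- check_scalar(n_pixels, "n_pixels", 1, integerish = TRUE)
  if (!is.numeric(adu) || length(adu) == 0L || any(!is.finite(adu)))
    stop_invalid("adu must be finite numeric")
  if (any(adu < 0))
    stop_invalid("negative observed adu (", min(adu),
                 "): the Gaussian CCD model does not apply")
  ccd$gain * adu + ccd$gain^2 * n_pixels * ccd$readout_variance
}
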