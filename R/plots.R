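#' Diagnostic plots for a validation run
#'
#' `plot_transient_estimates()` draws the normalized residuals (top) and the
#' estimated transient with its error bars over the true calcium time course
#' (bottom).  `plot_ecdf_band()` draws the ECDF of the normalized residuals
#' with the standard normal CDF and simultaneous Kolmogorov bands.
#'
#' @param report a `fura_validation` object from [run_validation()].
#' @param alphas band levels for `plot_ecdf_band()`.
#' @return invisibly `NULL`; called for the side effect.
#' @name fura-plots
NULL

#' @rdname fura-plots
#' @export
plot_transient_estimates <- function(report) {
  stopifnot(inherits(report, "fura_validation"))
  est <- report$estimates
  v <- est$valid
  s <- if (report$se_method == "mc") est$se_mc else est$se_delta
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(est$time[v], report$residuals, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "normalized residual",
                 main = "Standardized residuals")
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey40")
  graphics::plot(est$time[v], est$ca[v], type = "n", xlab = "time (s)",
                 ylab = "[Ca2+] (uM)", main = "Estimate vs truth")
  graphics::arrows(est$time[v], est$ca[v] - s[v], est$time[v],
                   est$ca[v] + s[v], length = 0.01, angle = 90, code = 3,
                   col = "grey50")
  graphics::points(est$time[v], est$ca[v], pch = 16, cex = 0.4)
  graphics::lines(est$time[v], report$true_ca[v], col = "red", lwd = 1.5)
  invisible(NULL)
}

#' @rdname fura-plots
#' @export
plot_ecdf_band <- function(report, alphas = c(0.05, 0.01)) {
  stopifnot(inherits(report, "fura_validation"))
  res <- report$residuals
  n <- length(res)
  xs <- seq(min(res) - 0.5, max(res) + 0.5, length.out = 400)
  graphics::plot(xs, stats::pnorm(xs), type = "l", lwd = 1.5,
                 xlab = "normalized residual", ylab = "CDF",
                 main = "ECDF vs standard normal with Kolmogorov bands")
  cols <- c("grey70", "skyblue")
  for (i in seq_along(alphas)) {
    hw <- as.numeric(kolmogorov_band(n, alphas[i]))
    graphics::lines(xs, pmin(1, stats::pnorm(xs) + hw), col = cols[i])
    graphics::lines(xs, pmax(0, stats::pnorm(xs) - hw), col = cols[i])
  }
  graphics::lines(stats::ecdf(res), col = "red", do.points = FALSE)
  graphics::legend("topleft", bty = "n", lwd = 1,
                   col = c("black", "red", cols[seq_along(alphas)]),
                   legend = c("N(0,1)", "ECDF",
                              sprintf("%g%% band", 100 * (1 - alphas))))
  invisible(NULL)
}
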