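#' Normalized residuals of a calcium transient estimate
#'
#' Elementwise `(ca - true_ca) / se`.  When the standard errors are correct
#' these are draws from a standard normal distribution — the basis of the
#' whole validation pipeline.
#'
#' @param estimates a `fura_estimates` data frame from [estimate_transient()].
#' @param true_ca ground-truth calcium vector (uM), same length.
#' @param se which standard error to normalize by: `"mc"` (default) or
#'   `"delta"`.
#' @return dimensionless residual vector.
#' @export
normalized_residuals <- function(estimates, true_ca, se = c("mc", "delta")) {
  se <- match.arg(se)
  if (nrow(estimates) != length(true_ca))
    stop_invalid("estimates (", nrow(estimates), ") and true_ca (",
                 length(true_ca), ") lengths differ")
  if (!all(estimates$valid))
    stop_invalid("invalid estimate at index ",
                 which(!estimates$valid)[1L])
  s <- if (se == "mc") estimates$se_mc else estimates$se_delta
  bad <- which(!is.finite(s) | s <= 0)
  if (length(bad))
    stop_invalid("non-positive or missing standard error at index ", bad[1L])
  (estimates$ca - true_ca) / s
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk routine with the input
#' checks this package needs (sample size 3..5000, non-degenerate sample).
#'
#' @param residuals numeric sample.
#' @return a list with `w` (the W statistic, in (0, 1]) and `p` (p-value).
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || n > 5000L)
    stop_invalid("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (any(!is.finite(residuals))) stop_invalid("non-finite residual")
  if (diff(range(residuals)) == 0)
    stop_invalid("degenerate sample: all values identical")
  sw <- stats::shapiro.test(residuals)
  list(w = unname(sw$statistic), p = sw$p.value)
}

# P(D_n < d) for the one-sample Kolmogorov-Smirnov statistic, exact for
# finite n (Marsaglia, Tsang & Wang 2003 evaluation of Durbin's matrix
# formula), with periodic rescaling to avoid overflow.
kolmogorov_cdf_exact <- function(n, d) {
  if (d <= 1 / (2 * n)) return(0)
  if (d >= 1) return(1)
  k <- ceiling(n * d)
  m <- 2L * k - 1L
  h <- k - n * d
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i - j + 1L >= 0L) H[i, j] <- 1
  for (i in seq_len(m)) {
    H[i, 1L] <- H[i, 1L] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1L)
  }
  H[m, 1L] <- H[m, 1L] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i - j + 1L > 0L) H[i, j] <- H[i, j] / factorial(i - j + 1L)
  # H^n by repeated squaring, tracking a power-of-1e140 exponent
  eH <- 0
  Q <- diag(m); eQ <- 0
  P <- H; eP <- eH; e <- n
  while (e > 0) {
    if (e %% 2 == 1) {
      Q <- Q %*% P; eQ <- eQ + eP
      if (Q[k, k] > 1e140) { Q <- Q / 1e140; eQ <- eQ + 140 }
    }
    P <- P %*% P; eP <- 2 * eP
    if (P[k, k] > 1e140) { P <- P / 1e140; eP <- eP + 140 }
    e <- e %/% 2
  }
  # result = n!/n^n * Q[k,k] * 10^eQ
  lres <- lgamma(n + 1) - n * log(n) + log(Q[k, k]) + eQ * log(10)
  min(1, max(0, exp(lres)))
}

# limiting Kolmogorov CDF: P(sqrt(n) D_n <= x) as n -> infinity
kolmogorov_cdf_asymptotic <- function(x) {
  if (x <= 0) return(0)
  j <- seq_len(101)
  max(0, min(1, 1 - 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))))
}

#' Half-width of a Kolmogorov confidence band
#'
#' Simultaneous band for an empirical CDF: the ECDF of a size-`n` sample
#' from the true distribution stays *entirely* within plus/minus the
#' returned half-width of the true CDF with probability `1 - alpha` (a
#' confidence band, not a collection of pointwise intervals).  For
#' `n <= 1000` the half-width is the exact finite-n quantile of the
#' Kolmogorov-Smirnov statistic; for larger `n` the asymptotic
#' \eqn{c(\alpha)/\sqrt{n}} quantile is used (c = 1.358 at 5%, 1.628 at 1%).
#'
#' @param n sample size, >= 1.
#' @param alpha band level in (0, 1); the band misses with probability
#'   `alpha`.
#' @param method `"auto"` (default: exact for `n <= 1000`), `"exact"` or
#'   `"asymptotic"`.
#' @return band half-width (dimensionless, on the CDF scale), with
#'   attribute `"method"` recording which construction was used.
#' @export
#' @examples
#' kolmogorov_band(200, 0.05)
#' 1.358 / sqrt(200)  # asymptotic counterpart
kolmogorov_band <- function(n, alpha, method = c("auto", "exact",
                                                 "asymptotic")) {
  method <- match.arg(method)
  n <- check_scalar(n, "n", 1, integerish = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop_invalid("alpha must be in (0, 1)")
  if (method == "auto") method <- if (n <= 1000) "exact" else "asymptotic"
  hw <- if (method == "exact") {
    stats::uniroot(function(d) kolmogorov_cdf_exact(n, d) - (1 - alpha),
                   lower = 1 / (2 * n) + 1e-12, upper = 1 - 1e-12,
                   tol = 1e-10)$root
  } else {
    stats::uniroot(function(x) kolmogorov_cdf_asymptotic(x) - (1 - alpha),
                   lower = 1e-4, upper = 5, tol = 1e-10)$root / sqrt(n)
  }
  structure(hw, method = method)
}

#' Check an ECDF against a Kolmogorov band around the standard normal CDF
#'
#' Computes the Kolmogorov-Smirnov sup-norm distance between the empirical
#' CDF of `residuals` and the standard normal CDF (evaluating both
#' one-sided limits at every jump) and compares it with the
#' [kolmogorov_band()] half-width.
#'
#' @param residuals nonempty numeric sample.
#' @param alpha band level, as in [kolmogorov_band()].
#' @param method band construction, passed to [kolmogorov_band()].
#' @return list with `inside` (logical), `max_deviation`, `half_width`, and
#'   `band_method`.
#' @export
ecdf_band_check <- function(residuals, alpha = 0.05, method = "auto") {
  n <- length(residuals)
  if (n < 1L) stop_invalid("empty residuals")
  x <- sort(residuals)
  fr <- stats::pnorm(x)
  i <- seq_len(n)
  dev <- max(pmax(i / n - fr, fr - (i - 1) / n))
  hw <- kolmogorov_band(n, alpha, method)
  list(inside = dev <= as.numeric(hw), max_deviation = dev,
       half_width = as.numeric(hw), band_method = attr(hw, "method"))
}

#' Weighted monoexponential fit of a calcium transient
#'
#' Fits \eqn{Ca(t) = Ca_0 + \delta e^{-(t-t_0)/\tau}} to the estimated
#' transient by weighted nonlinear least squares, minimizing
#' \eqn{\sum_i \left((\widehat{Ca}_i - Ca(t_i;\theta))/\hat\sigma_i\right)^2}
#' with the per-point standard errors as weights.  Because the errors grow
#' with calcium, an unweighted fit would be driven by the noisy high-calcium
#' points; the weighted fit yields honest parameter confidence intervals.
#'
#' `t0` is fixed (normally known from the stimulus time): on decay-only
#' data `t0` and `delta` are strongly confounded, and a free `t0` mostly
#' trades off against amplitude.  Set `fit_t0 = TRUE` to free it anyway.
#'
#' By default the fit is performed twice.  The per-point standard errors
#' are estimated from the same noisy counts as the calcium values, so a
#' point that fluctuates low also receives a slightly smaller error
#' estimate — hence more weight — which biases the raw plug-in-weighted
#' fit downward (about half a standard error on the baseline for the
#' packaged parameters).  The second pass therefore replaces the raw
#' weights by a smooth function of the *fitted* calcium (a log-quadratic
#' regression of the squared SE on the fitted value), which carries the
#' same information — the error profile along the transient — without the
#' point-level noise correlation.  Set `reweight = FALSE` for the raw
#' single-pass plug-in weighting.
#'
#' Parameter standard errors come from the local quadratic expansion of the
#' weighted objective at the optimum, i.e. \eqn{(J^T W J)^{-1}} *without*
#' rescaling by the reduced chi-square — the weights are true standard
#' errors, not relative ones, so the residual scale is known to be 1.
#'
#' @param estimates a `fura_estimates` data frame (needs >= 5 valid points
#'   with positive standard errors).
#' @param t0 event time (s) at which the decay starts.
#' @param se which standard error weights the fit: `"mc"` or `"delta"`.
#' @param fit_t0 also estimate `t0` (default `FALSE`).
#' @param reweight smooth the weights along the fitted curve in a second
#'   pass (default `TRUE`; see Details).
#' @param start optional named list overriding the self-derived starting
#'   values (`ca0`, `delta`, `tau`, and `t0` if freed).
#' @return list of class `fura_fit` with `estimate` (a [decay_params()]),
#'   `se` (named vector), `cov` (parameter covariance), `chisq` (weighted
#'   residual sum of squares), `df` (residual degrees of freedom), `n`,
#'   and `fitted`.
#' @export
fit_monoexp_weighted <- function(estimates, t0, se = c("mc", "delta"),
                                 fit_t0 = FALSE, reweight = TRUE,
                                 start = NULL) {
  se <- match.arg(se)
  s <- if (se == "mc") estimates$se_mc else estimates$se_delta
  keep <- estimates$valid & is.finite(s) & s > 0 & is.finite(estimates$ca)
  if (sum(keep) < 5L)
    stop_invalid("need >= 5 valid points with positive SE (got ",
                 sum(keep), ")")
  t0 <- check_scalar(t0, "t0")
  tt <- estimates$time[keep]; ca <- estimates$ca[keep]; s <- s[keep]
  w <- 1 / s^2
  # self-derived starting values: baseline from the tail, amplitude from the
  # head, tau from a log-linear regression of the positive excess
  n_tail <- max(3L, ceiling(0.1 * length(ca)))
  ca0_0 <- mean(utils::tail(ca, n_tail))
  delta_0 <- max(ca[1L] - ca0_0, 1e-4)
  pos <- ca - ca0_0 > delta_0 * 0.05
  tau_0 <- if (sum(pos) >= 3L) {
    sl <- stats::coef(stats::lm(log(ca[pos] - ca0_0) ~ tt[pos]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tt)) / 5
  } else diff(range(tt)) / 5
  st <- list(ca0 = ca0_0, delta = delta_0, tau = tau_0)
  if (fit_t0) st$t0 <- t0
  if (!is.null(start)) st[names(start)] <- start
  fml <- if (fit_t0) ca ~ ca0 + delta * exp(-(tt - t0) / tau) else
    ca ~ ca0 + delta * exp(-(tt - .t0) / tau)
  .t0 <- t0
  env <- environment()
  run_nls <- function(w_vec, start) tryCatch({
    env$.wfit <- w_vec  # nls evaluates `weights` in the formula environment
    stats::nls(fml, start = start, weights = .wfit, algorithm = "port",
               lower = c(ca0 = -Inf, delta = 0, tau = 1e-6,
                         if (fit_t0) c(t0 = -Inf))[names(start)],
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE))
  }, error = function(e) stop(errorCondition(
      paste0("monoexponential fit failed to converge: ",
             conditionMessage(e), " (start: ca0=", signif(st$ca0, 4),
             ", delta=", signif(st$delta, 4), ", tau=", signif(st$tau, 4),
             ")"),
      class = c("fura_fit_failure", "error"))))
  fit <- run_nls(w, st)
  if (reweight) {
    # decorrelate weights from point-level noise: smooth squared SE along
    # the fitted transient, then refit from the first-pass optimum
    mu <- stats::fitted(fit)
    s2fit <- stats::lm(log(s^2) ~ mu + I(mu^2))
    w <- 1 / exp(stats::fitted(s2fit))
    fit <- run_nls(w, as.list(stats::coef(fit)))
  }
  cf <- stats::coef(fit)
  covu <- summary(fit)$cov.unscaled  # (J' W J)^-1, unscaled: weights are
                                     # absolute standard errors
  ses <- sqrt(diag(covu))
  est <- decay_params(t0 = if (fit_t0) cf[["t0"]] else t0,
                      ca0 = cf[["ca0"]], delta = max(cf[["delta"]], 0),
                      tau = cf[["tau"]])
  structure(list(estimate = est, se = ses, cov = covu,
                 chisq = sum(w * stats::resid(fit)^2),
                 df = length(ca) - length(cf), n = length(ca),
                 fitted = stats::fitted(fit), se_method = se),
            class = "fura_fit")
}

#' @export
print.fura_fit <- function(x, ...) {
  e <- x$estimate
  cat("Weighted monoexponential fit (Ca0 + delta exp(-(t-t0)/tau))\n")
  cat(sprintf("  ca0   = %.4g +/- %.3g uM\n", e$ca0, x$se[["ca0"]]))
  cat(sprintf("  delta = %.4g +/- %.3g uM\n", e$delta, x$se[["delta"]]))
  cat(sprintf("  tau   = %.4g +/- %.3g s\n", e$tau, x$se[["tau"]]))
  if ("t0" %in% names(x$se))
    cat(sprintf("  t0    = %.6g +/- %.3g s\n", e$t0, x$se[["t0"]]))
  cat(sprintf("  chi-square %.1f on %d df (n = %d, %s-method weights)\n",
              x$chisq, x$df, x$n, x$se_method))
  invisible(x)
}

#' End-to-end standard-error validation run
#'
#' Simulates a transient with known calcium dynamics, estimates it exactly
#' as real data would be (background subtraction, ratio, calcium transform,
#' Monte-Carlo standard errors), and tests the normalized residuals against
#' the standard normal distribution: Shapiro-Wilk test plus ECDF checks
#' against 95% and 99% Kolmogorov bands.  If the standard errors are
#' correctly calibrated the residuals are N(0, 1); a residual SD far from 1
#' reveals mis-scaled errors even when the shape stays normal.
#'
#' @param params parameter list as returned by [fura_default_params()]
#'   (elements `acquisition`, `illumination`, `decay`); defaults to the
#'   packaged reference values.
#' @param times sampling grid (s); default [decay_grid()] of the decay
#'   parameters (0.15 s sampling over 30 s past the event).
#' @param k Monte-Carlo draws per point (default 10^4).
#' @param seed integer seed for the whole run (simulation plus Monte-Carlo).
#' @param se standard error used for the residuals: `"mc"` (default) or
#'   `"delta"`.
#' @param alphas band levels to check (default 0.05 and 0.01).
#' @return a list of class `fura_validation`: `residuals`, `n_points`,
#'   `mean`, `sd`, `sw_w`, `sw_p`, `band_95_ok`, `band_99_ok`, `bands`
#'   (per-level detail), `estimates`, `true_ca`, `se_method`, `k`, `seed`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_validation(seed = 42, k = 2000)
#' rep
#' }
run_validation <- function(params = fura_default_params(), times = NULL,
                           k = 10000L, seed = 1L, se = c("mc", "delta"),
                           alphas = c(0.05, 0.01)) {
  se <- match.arg(se)
  if (is.null(times)) times <- decay_grid(params$decay)
  set.seed(as.integer(seed))
  sim <- simulate_transient(times, params$decay, params$illumination,
                            params$acquisition)
  method <- if (se == "mc") "mc" else "delta"
  est <- estimate_transient(sim$series, params$acquisition, method = method,
                            k = k)
  res <- normalized_residuals(est, sim$true_ca, se = se)
  sw <- shapiro_wilk(res)
  bands <- lapply(alphas, function(a) {
    c(list(alpha = a), ecdf_band_check(res, a))
  })
  names(bands) <- paste0("alpha_", alphas)
  get_ok <- function(a) {
    i <- which(vapply(bands, function(b) b$alpha == a, logical(1)))
    if (length(i)) bands[[i]]$inside else NA
  }
  structure(list(
    residuals = res, n_points = length(res),
    mean = mean(res), sd = stats::sd(res),
    sw_w = sw$w, sw_p = sw$p,
    band_95_ok = get_ok(0.05), band_99_ok = get_ok(0.01),
    bands = bands, estimates = est, true_ca = sim$true_ca,
    se_method = se, k = as.integer(k), seed = as.integer(seed)
  ), class = "fura_validation")
}

#' @export
print.fura_validation <- function(x, ...) {
  cat(sprintf("Standard-error validation (%d points, %s method, k = %d, seed = %d)\n",
              x$n_points, x$se_method, x$k, x$seed))
  cat(sprintf("  residuals: mean %.3f, SD %.3f\n", x$mean, x$sd))
  cat(sprintf("  Shapiro-Wilk: W = %.4f, p = %.4f\n", x$sw_w, x$sw_p))
  for (b in x$bands)
    cat(sprintf("  %2.0f%% Kolmogorov band (%s): %s (max dev %.4f, half-width %.4f)\n",
                100 * (1 - b$alpha), b$band_method,
                if (b$inside) "inside" else "OUTSIDE",
                b$max_deviation, b$half_width))
  invisible(x)
}
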