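#' Fit an allometric power law by log-log least squares
#'
#' Fits `rate = c * mass^exponent` as ordinary least squares of
#' log10(rate) on log10(mass). This is the conventional estimate of the
#' Kleiber exponent (whole-organism metabolic rate B scales roughly as
#' M^(3/4), so the mass-specific rate B_c = B / M scales as M^(-1/4)).
#' The correlation and its two-sided p-value come from the Pearson
#' correlation of the logged variables (t statistic with n - 2 df).
#'
#' @param mass positive numeric vector of body masses (g).
#' @param rate positive numeric vector of rates (same length).
#' @return object of class `allometric_fit`: list with `exponent`,
#'   `exponent_se`, `intercept_log10`, `r`, `p_value`, `n`.
#' @examples
#' fit_power_law(c(1, 10, 100, 1000), 3 * c(1, 10, 100, 1000)^0.75)
#' @export
fit_power_law <- function(mass, rate) {
  if (length(mass) != length(rate)) stop("mass and rate must have equal length")
  n <- length(mass)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(mass)) || any(!is.finite(rate)) ||
      any(mass <= 0) || any(rate <= 0)) {
    stop("mass and rate must be positive and finite")
  }
  x <- log10(mass)
  y <- log10(rate)
  if (stats::var(x) == 0) stop("zero variance in log mass")
  if (stats::var(y) == 0) stop("zero variance in log rate (degenerate fit)")
  fit <- stats::lm(y ~ x)
  # slope SE computed directly so a perfect fit stays silent
  rss <- sum(stats::resid(fit)^2)
  se <- sqrt(rss / (n - 2L) / sum((x - mean(x))^2))
  ct <- stats::cor.test(x, y)
  structure(list(
    exponent = unname(stats::coef(fit)[2L]),
    exponent_se = se,
    intercept_log10 = unname(stats::coef(fit)[1L]),
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = n
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("Allometric power-law fit (log10-log10 OLS)\n")
  cat(sprintf("  exponent : %.4f +/- %.4f (SE)\n", x$exponent, x$exponent_se))
  cat(sprintf("  intercept: 10^%.4f\n", x$intercept_log10))
  cat(sprintf("  Pearson r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.allometric_fit <- function(object, ...) {
  c(intercept_log10 = object$intercept_log10, exponent = object$exponent)
}

#' @export
confint.allometric_fit <- function(object, parm = "exponent", level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$n - 2L)
  m <- matrix(c(object$exponent - tq * object$exponent_se,
                object$exponent + tq * object$exponent_se), nrow = 1L)
  dimnames(m) <- list("exponent",
                      sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  m
}
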