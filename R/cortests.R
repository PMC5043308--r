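#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson r with the usual two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 df. Errors identify
#' which input is degenerate (zero variance), rather than returning NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("zero variance in x")
  if (stats::var(y) == 0) stop("zero variance in y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` with `z` held constant:
#' `r_p = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' with a two-sided p-value from a t statistic on n - 3 df (one
#' conditioning variable). Identical to the Pearson correlation of the
#' OLS residuals of `x` on `z` and of `y` on `z`.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @param df degrees of freedom for the t test; defaults to n - 3.
#'   (Contrast-based analyses pass a reduced df.)
#' @return list with `r` and `p`.
#' @export
partial_cor <- function(x, y, z, df = length(x) - 3L) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (!is.finite(r_xz) || !is.finite(r_yz)) stop("degenerate conditioning variable")
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("perfect collinearity with the conditioning variable; partial correlation undefined")
  }
  r_p <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r_p <- max(-1, min(1, r_p))
  tt <- r_p * sqrt(df) / sqrt(max(1 - r_p^2, .Machine$double.eps))
  list(r = r_p, p = 2 * stats::pt(-abs(tt), df = df))
}

#' OLS residuals of y on x (with intercept)
#'
#' @param y response vector.
#' @param x single predictor, nonconstant.
#' @return numeric residual vector (sums to 0, orthogonal to `x`).
#' @export
ols_residuals <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (stats::var(x) == 0) stop("constant predictor: residuals undefined")
  unname(stats::resid(stats::lm(y ~ x)))
}

#' Standardized partial regression coefficient for body mass
#'
#' Fits `g ~ logM + logBc` by OLS and returns the coefficient of `logM`
#' rescaled to standard-deviation units, `b_M * sd(logM) / sd(g)` — the
#' B_c-corrected estimate of the body-mass effect on a gene count.
#'
#' @param g response (gene counts, untransformed).
#' @param logM,logBc predictors.
#' @return standardized coefficient (scalar).
#' @export
std_partial_beta <- function(g, logM, logBc) {
  n <- length(g)
  if (length(logM) != n || length(logBc) != n) stop("inputs must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  fit <- stats::lm(g ~ logM + logBc)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: logM and logBc are collinear")
  }
  unname(stats::coef(fit)["logM"] * stats::sd(logM) / stats::sd(g))
}
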