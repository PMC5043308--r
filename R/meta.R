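#' Mean and 95% CI of a per-category correlation distribution
#'
#' Arithmetic mean of the chosen correlation field across categories with a
#' 95% confidence interval, by normal approximation
#' (mean +/- 1.96 sd / sqrt(k)) or bootstrap percentile. Flagged
#' (undefined) categories are excluded and counted.
#'
#' @param object an `nogf_scan` or results data frame.
#' @param field `"r_M"` or `"r_partial"`.
#' @param ci_method `"normal"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (bootstrap method only).
#' @return list: `mean`, `ci95_low`, `ci95_high`, `k` (values used),
#'   `n_excluded`.
#' @export
summarize_r_distribution <- function(object, field = c("r_M", "r_partial"),
                                     ci_method = c("normal", "bootstrap"),
                                     n_boot = 2000L) {
  field <- match.arg(field)
  ci_method <- match.arg(ci_method)
  r <- scan_results(object)[[field]]
  excl <- sum(is.na(r))
  r <- r[!is.na(r)]
  k <- length(r)
  if (k < 2L) stop("need at least 2 defined correlation values")
  m <- mean(r)
  if (ci_method == "normal") {
    half <- 1.96 * stats::sd(r) / sqrt(k)
    lo <- m - half; hi <- m + half
  } else {
    bm <- replicate(n_boot, mean(sample(r, k, replace = TRUE)))
    qs <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  list(mean = m, ci95_low = lo, ci95_high = hi, k = k, n_excluded = excl)
}

#' @rdname summarize_r_distribution
#' @export
summarize_r <- summarize_r_distribution

#' Count and fraction of significant categories
#'
#' Strict inequality p < alpha, over categories with a defined p-value.
#'
#' @param object an `nogf_scan` or results data frame.
#' @param field `"p_M"` or `"p_partial"`.
#' @param alpha significance threshold in (0, 1).
#' @return list: `count`, `fraction`, `n` (defined p-values).
#' @export
significant_fraction <- function(object, field = c("p_M", "p_partial"),
                                 alpha = 0.05) {
  field <- match.arg(field)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- scan_results(object)[[field]]
  p <- p[!is.na(p)]
  n <- length(p)
  count <- sum(p < alpha)
  list(count = count, fraction = if (n > 0L) count / n else NA_real_, n = n)
}

#' Correlation of correlations (confound diagnostic)
#'
#' Pearson correlation, across functional categories, between the NOGF-M
#' correlation vector and the NOGF-B_c correlation vector. If NOGF-M
#' associations are driven by the mass-specific metabolic rate through its
#' tight negative coupling with body mass, this meta-correlation is
#' strongly negative. Categories with undefined correlations are excluded
#' (their count is returned).
#'
#' @param object an `nogf_scan` or results data frame.
#' @return list: `r`, `p`, `k` (categories used), `n_excluded`.
#' @export
meta_correlation <- function(object) {
  res <- scan_results(object)
  ok <- !is.na(res$r_M) & !is.na(res$r_Bc)
  if (sum(ok) < 3L) stop("need at least 3 categories with defined correlations")
  ct <- pearson_cor(res$r_M[ok], res$r_Bc[ok])
  list(r = ct$r, p = ct$p, k = sum(ok), n_excluded = sum(!ok))
}

#' Write a one-row meta summary as TSV
#'
#' @param s a `summary.nogf_scan`.
#' @param path output path.
#' @param variant label for the row (e.g. "ols", "pic").
#' @export
write_meta_summary <- function(s, path, variant = s$method) {
  df <- data.frame(
    variant = variant,
    n_species = s$n_species, n_categories = s$n_categories,
    n_flagged = s$n_flagged, alpha = s$alpha,
    mean_r = s$r_M$mean, r_ci95_low = s$r_M$ci95_low,
    r_ci95_high = s$r_M$ci95_high,
    mean_r_partial = s$r_partial$mean,
    rp_ci95_low = s$r_partial$ci95_low, rp_ci95_high = s$r_partial$ci95_high,
    n_significant = s$sig_M$count, frac_significant = s$sig_M$fraction,
    n_significant_partial = s$sig_partial$count,
    frac_significant_partial = s$sig_partial$fraction,
    meta_corr_r = s$meta_corr$r, meta_corr_p = s$meta_corr$p
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
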