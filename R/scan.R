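#' Scan functional-category gene counts against body mass
#'
#' The central fitting function. For every functional category it
#' associates the per-species gene count (NOGF, used untransformed) with
#' log10 body mass M and log10 mass-specific metabolic rate B_c:
#'
#' * `r_M`, `p_M`: simple Pearson correlation of NOGF with log10 M;
#' * `r_Bc`, `p_Bc`: Pearson correlation with log10 B_c;
#' * `r_partial`, `p_partial`: first-order partial correlation of NOGF
#'   with log10 M holding log10 B_c constant (the B_c-corrected
#'   association; t test on n - 3 df);
#' * `beta_M_std`: standardized partial regression coefficient of log10 M
#'   in the multivariate fit NOGF ~ log10 M + log10 B_c;
#' * `r2_simple = r_M^2`, `r2_corrected = r_partial^2`.
#'
#' With `method = "pic"` all three variables are first transformed into
#' phylogenetically independent contrasts on `tree` and the correlations
#' are computed through the origin (see [compute_contrasts()] and
#' [corr_through_origin()]); partial correlations then use k - 2 df for k
#' contrasts, and `beta_M_std` is not defined.
#'
#' Species are matched by id across the count matrix, the species table
#' and (for PIC) the tree; non-overlapping species are dropped with a
#' warning (as when a species present in the trait data is absent from the
#' tree). Categories with zero count variance are retained as flagged rows
#' (`defined = FALSE`) with NA statistics rather than dropped silently.
#'
#' @param counts NOGF matrix, species as rows, categories as columns.
#' @param species species table (see [validate_species_table()]).
#' @param hierarchy optional named character vector mapping category to
#'   upper category (used by [enrich()] and reported in the results).
#' @param method `"ols"` (ordinary cross-species scan) or `"pic"`.
#' @param tree `phylo` tree, required for `method = "pic"`.
#' @param alpha significance threshold carried into summaries.
#' @param p_adjust `"none"` (default; raw p-values, as in a scan that
#'   reports p < 0.05 directly) or `"BH"` to append Benjamini-Hochberg
#'   adjusted columns `q_M`, `q_partial`.
#' @return object of class `nogf_scan`: list with `results` (one row per
#'   category), `n` (species used), `method`, `alpha`, `dropped_species`,
#'   `n_flagged`, `hierarchy`.
#' @seealso [summary.nogf_scan()], [top_table()], [enrich()],
#'   [meta_correlation()]
#' @export
nogf_scan <- function(counts, species, hierarchy = NULL,
                      method = c("ols", "pic"), tree = NULL,
                      alpha = 0.05, p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  validate_function_matrix(counts)
  validate_species_table(species)
  if (method == "pic" && is.null(tree)) stop("method = 'pic' requires a tree")

  common <- intersect(rownames(counts), species$species_id)
  if (method == "pic") common <- intersect(common, tree$tip.label)
  dropped <- setdiff(unique(c(rownames(counts), species$species_id)), common)
  if (length(dropped) > 0L) {
    warning(length(dropped), " species dropped (absent from matrix, table",
            if (method == "pic") " or tree", "): ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ...")
  }
  if (length(common) < 4L) stop("fewer than 4 species shared by the inputs")
  common <- sort(common)

  sp <- species[match(common, species$species_id), ]
  cnt <- counts[common, , drop = FALSE]
  logM <- log10(sp$body_mass_g)
  logBc <- log10(sp$mass_specific_rate_Wg)

  res <- if (method == "ols") {
    scan_ols(cnt, logM, logBc)
  } else {
    scan_pic(cnt, logM, logBc, tree, common)
  }
  res$upper_category_id <- if (is.null(hierarchy)) NA_character_ else
    unname(hierarchy[res$category_id])
  res$r2_simple <- res$r_M^2
  res$r2_corrected <- res$r_partial^2
  res <- res[, c("category_id", "upper_category_id", "r_M", "p_M", "r_Bc",
                 "p_Bc", "r_partial", "p_partial", "beta_M_std",
                 "r2_simple", "r2_corrected", "n", "defined")]
  if (p_adjust == "BH") {
    res$q_M <- stats::p.adjust(res$p_M, method = "BH")
    res$q_partial <- stats::p.adjust(res$p_partial, method = "BH")
  }
  structure(list(
    results = res,
    n = length(common),
    method = method,
    alpha = alpha,
    dropped_species = dropped,
    n_flagged = sum(!res$defined),
    hierarchy = hierarchy
  ), class = "nogf_scan")
}

# per-category OLS-scale scan on the tip data
scan_ols <- function(cnt, logM, logBc) {
  n <- length(logM)
  one <- function(g) {
    if (stats::var(g) == 0) {
      return(data.frame(r_M = NA_real_, p_M = NA_real_, r_Bc = NA_real_,
                        p_Bc = NA_real_, r_partial = NA_real_,
                        p_partial = NA_real_, beta_M_std = NA_real_,
                        n = n, defined = FALSE))
    }
    cm <- pearson_cor(g, logM)
    cb <- pearson_cor(g, logBc)
    pc <- partial_cor(g, logM, logBc)
    data.frame(r_M = cm$r, p_M = cm$p, r_Bc = cb$r, p_Bc = cb$p,
               r_partial = pc$r, p_partial = pc$p,
               beta_M_std = std_partial_beta(g, logM, logBc),
               n = n, defined = TRUE)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(cnt)), function(j) one(cnt[, j])))
  out$category_id <- colnames(cnt)
  out
}

# contrast-based scan: correlations through the origin, reduced df
scan_pic <- function(cnt, logM, logBc, tree, common) {
  if (length(setdiff(tree$tip.label, common)) > 0L) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  }
  cM <- compute_contrasts(tree, stats::setNames(logM, common), label = "logM")
  cBc <- compute_contrasts(tree, stats::setNames(logBc, common), label = "logBc")
  k <- length(cM$contrasts)
  r_MBc <- corr_through_origin(cM, cBc)$r
  one <- function(g, id) {
    cg <- compute_contrasts(tree, stats::setNames(g, common), label = id)
    if (sum(cg$contrasts^2) == 0) {
      return(data.frame(r_M = NA_real_, p_M = NA_real_, r_Bc = NA_real_,
                        p_Bc = NA_real_, r_partial = NA_real_,
                        p_partial = NA_real_, beta_M_std = NA_real_,
                        n = k, defined = FALSE))
    }
    om <- corr_through_origin(cg, cM)
    ob <- corr_through_origin(cg, cBc)
    rp <- partial_from_r(om$r, ob$r, r_MBc, df = k - 2L)
    data.frame(r_M = om$r, p_M = om$p, r_Bc = ob$r, p_Bc = ob$p,
               r_partial = rp$r, p_partial = rp$p, beta_M_std = NA_real_,
               n = k, defined = TRUE)
  }
  out <- do.call(rbind, lapply(seq_len(ncol(cnt)),
                               function(j) one(cnt[, j], colnames(cnt)[j])))
  out$category_id <- colnames(cnt)
  out
}

# first-order partial correlation from the three pairwise correlations
partial_from_r <- function(r_xy, r_xz, r_yz, df) {
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("perfect collinearity; partial correlation undefined")
  }
  r_p <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r_p <- max(-1, min(1, r_p))
  tt <- r_p * sqrt(df) / sqrt(max(1 - r_p^2, .Machine$double.eps))
  list(r = r_p, p = 2 * stats::pt(-abs(tt), df = df))
}

#' @export
print.nogf_scan <- function(x, ...) {
  cat(sprintf("NOGF scan (%s), %d species, %d categories (%d flagged undefined)\n",
              x$method, x$n, nrow(x$results), x$n_flagged))
  sf_m <- significant_fraction(x, "p_M", x$alpha)
  sf_p <- significant_fraction(x, "p_partial", x$alpha)
  cat(sprintf("  significant NOGF-M (p < %g):  %d/%d (%.1f%%) uncorrected, %d/%d (%.1f%%) B_c-corrected\n",
              x$alpha, sf_m$count, sf_m$n, 100 * sf_m$fraction,
              sf_p$count, sf_p$n, 100 * sf_p$fraction))
  invisible(x)
}

#' Dataset-level summary of a NOGF scan
#'
#' Computes the distribution summaries of the per-category correlations:
#' mean r with a normal-approximation 95% CI, significant fractions at the
#' scan's alpha (uncorrected and B_c-corrected), and the
#' correlation-of-correlations confound diagnostic (Pearson correlation,
#' across categories, between the NOGF-M and NOGF-B_c correlation
#' vectors; a strongly negative value indicates metabolic-rate-driven
#' associations).
#'
#' @param object an `nogf_scan`.
#' @param ci_method `"normal"` (mean +/- 1.96 sd/sqrt(k)) or
#'   `"bootstrap"` (percentile, 2000 resamples).
#' @param ... unused.
#' @return object of class `summary.nogf_scan`.
#' @export
summary.nogf_scan <- function(object, ci_method = c("normal", "bootstrap"), ...) {
  ci_method <- match.arg(ci_method)
  s_m <- summarize_r_distribution(object, "r_M", ci_method = ci_method)
  s_p <- summarize_r_distribution(object, "r_partial", ci_method = ci_method)
  f_m <- significant_fraction(object, "p_M", object$alpha)
  f_p <- significant_fraction(object, "p_partial", object$alpha)
  mc <- meta_correlation(object)
  structure(list(
    method = object$method, n_species = object$n,
    n_categories = nrow(object$results), n_flagged = object$n_flagged,
    alpha = object$alpha,
    r_M = s_m, r_partial = s_p,
    sig_M = f_m, sig_partial = f_p,
    meta_corr = mc
  ), class = "summary.nogf_scan")
}

#' @export
print.summary.nogf_scan <- function(x, ...) {
  cat(sprintf("NOGF scan summary (%s): %d species, %d categories (%d flagged)\n",
              x$method, x$n_species, x$n_categories, x$n_flagged))
  cat(sprintf("  mean r   (NOGF-M)            : %+.3f (95%% CI %+.3f .. %+.3f)\n",
              x$r_M$mean, x$r_M$ci95_low, x$r_M$ci95_high))
  cat(sprintf("  mean r_p (B_c-corrected)     : %+.3f (95%% CI %+.3f .. %+.3f)\n",
              x$r_partial$mean, x$r_partial$ci95_low, x$r_partial$ci95_high))
  cat(sprintf("  significant at p < %g        : %d/%d (%.1f%%) uncorrected, %d/%d (%.1f%%) corrected\n",
              x$alpha, x$sig_M$count, x$sig_M$n, 100 * x$sig_M$fraction,
              x$sig_partial$count, x$sig_partial$n, 100 * x$sig_partial$fraction))
  cat(sprintf("  corr(r_M, r_Bc) across categories: %+.3f (p = %.3g)\n",
              x$meta_corr$r, x$meta_corr$p))
  invisible(x)
}

#' @export
as.data.frame.nogf_scan <- function(x, ...) x$results

#' Histograms of the uncorrected and corrected correlation distributions
#'
#' @param x an `nogf_scan`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.nogf_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ok <- x$results$defined
  graphics::hist(x$results$r_M[ok], main = "NOGF-M correlation r",
                 xlab = "r", xlim = c(-1, 1), ...)
  graphics::hist(x$results$r_partial[ok], main = "B_c-corrected r_p",
                 xlab = expression(r[p]), xlim = c(-1, 1), ...)
  invisible(x)
}

#' Top B_c-corrected associations
#'
#' Filters categories with a corrected p-value below `p_threshold` and
#' orders them by descending partial correlation, ties broken by
#' category id (stable). Columns mirror a corrected-vs-uncorrected
#' comparison table: r_p with its p, then r with its p.
#'
#' @param object an `nogf_scan` or its results data frame.
#' @param p_threshold corrected-p cutoff (default 0.01).
#' @return data frame, possibly empty.
#' @export
top_table <- function(object, p_threshold = 0.01) {
  res <- scan_results(object)
  keep <- !is.na(res$p_partial) & res$p_partial < p_threshold
  out <- res[keep, c("upper_category_id", "category_id", "r_partial",
                     "p_partial", "r_M", "p_M")]
  out <- out[order(-out$r_partial, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# accept either the fitted object or the bare results table
scan_results <- function(object) {
  if (inherits(object, "nogf_scan")) object$results
  else if (is.data.frame(object)) object
  else stop("expected an nogf_scan object or results data frame")
}

#' Write scan results as TSV
#'
#' @param object an `nogf_scan` or results data frame.
#' @param path output path.
#' @export
write_scan_results <- function(object, path) {
  utils::write.table(scan_results(object), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
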