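#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test at odds ratio 1 for the table
#' `[[a, b], [c, d]]`. `sided = "greater"` gives the upper tail
#' (over-representation of significant categories inside the upper
#' category); `"two_sided"` sums all tables, with the margins fixed, whose
#' probability does not exceed that of the observed table (the convention
#' of `fisher.test`).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param sided `"greater"` or `"two_sided"`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("greater", "two_sided")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  if (sum(cells) < 1) stop("empty table")
  m <- matrix(as.integer(cells), nrow = 2L, byrow = TRUE)
  alternative <- if (sided == "greater") "greater" else "two.sided"
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Enrichment of significant categories within upper categories
#'
#' For each second-level (upper) functional category, builds the 2x2 table
#' inside-vs-outside x significant-vs-not, where "significant" means the
#' chosen per-category p-value (`p_M` for the uncorrected scan, `p_partial`
#' for the B_c-corrected scan) is below `alpha`, and tests
#' over-representation with Fisher's exact test. Categories with an
#' undefined p-value count as non-significant. The odds ratio is the
#' sample odds ratio (a d)/(b c) with a Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param object an `nogf_scan` or results data frame.
#' @param hierarchy named character vector category -> upper category;
#'   defaults to the scan's own hierarchy (or its `upper_category_id`
#'   column). Every scanned category must be mapped.
#' @param field `"p_M"` or `"p_partial"`.
#' @param alpha significance threshold (default 0.05).
#' @param sided passed to [fisher_exact_2x2()].
#' @return data frame of class `nogf_enrichment`, one row per upper
#'   category, sorted by `neg_log10_p` descending: columns
#'   `upper_category_id`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `neg_log10_p`.
#' @export
enrich <- function(object, hierarchy = NULL, field = c("p_M", "p_partial"),
                   alpha = 0.05, sided = c("greater", "two_sided")) {
  field <- match.arg(field)
  sided <- match.arg(sided)
  res <- scan_results(object)
  if (is.null(hierarchy) && inherits(object, "nogf_scan")) {
    hierarchy <- object$hierarchy
  }
  upper <- if (!is.null(hierarchy)) unname(hierarchy[res$category_id])
           else res$upper_category_id
  if (any(is.na(upper))) {
    stop("categories missing from the hierarchy: ",
         paste(utils::head(res$category_id[is.na(upper)], 10L), collapse = ", "))
  }
  p <- res[[field]]
  sig <- !is.na(p) & p < alpha
  total_sig <- sum(sig)
  total <- length(sig)
  rows <- lapply(sort(unique(upper)), function(u) {
    inside <- upper == u
    a <- sum(sig & inside)
    b <- sum(!sig & inside)
    cc <- total_sig - a
    d <- (total - sum(inside)) - cc
    or_cells <- c(a, b, cc, d)
    if (any(or_cells == 0)) or_cells <- or_cells + 0.5
    data.frame(upper_category_id = u, a = a, b = b, c = cc, d = d,
               odds_ratio = (or_cells[1] * or_cells[4]) /
                 (or_cells[2] * or_cells[3]),
               p_value = fisher_exact_2x2(a, b, cc, d, sided = sided))
  })
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(-out$neg_log10_p, out$upper_category_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nogf_enrichment", "data.frame")
  attr(out, "field") <- field
  attr(out, "alpha") <- alpha
  attr(out, "sided") <- sided
  out
}
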