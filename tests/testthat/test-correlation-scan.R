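test_that("pearson_cor matches the closed-form r and t-based p", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  out <- pearson_cor(x, y)
  # independent closed form
  r_exp <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_exp <- r_exp * sqrt(2) / sqrt(1 - r_exp^2)
  expect_equal(out$r, 0.6, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_exp), df = 2), tolerance = 1e-12)
  expect_equal(out$p, 0.4, tolerance = 0.0005)
  expect_error(pearson_cor(x, rep(1, 4)), "zero variance in y")
  expect_error(pearson_cor(rep(1, 4), y), "zero variance in x")
})

test_that("partial correlation reduces to simple correlation when z is orthogonal", {
  set.seed(11)
  x0 <- rnorm(12); y0 <- rnorm(12); w <- rnorm(12)
  z <- resid(lm(w ~ x0 + y0))       # orthogonal to both by construction
  pc <- partial_cor(x0, y0, z)
  expect_equal(pc$r, pearson_cor(x0, y0)$r, tolerance = 1e-10)
  expect_error(partial_cor(x0, y0, x0), "collinearity")
})

test_that("partial correlation equals the residual-residual Pearson correlation", {
  set.seed(12)
  for (i in 1:50) {
    z <- rnorm(50)
    x <- 0.8 * z + rnorm(50)
    y <- -0.5 * z + rnorm(50)
    pc <- partial_cor(x, y, z)
    rr <- cor(ols_residuals(x, z), ols_residuals(y, z))
    expect_equal(pc$r, rr, tolerance = 1e-10)
  }
})

test_that("ols_residuals satisfy the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(ols_residuals(2 * x, x), rep(0, 5), tolerance = 1e-12)
  set.seed(13)
  y <- rnorm(40); x <- rnorm(40)
  r <- ols_residuals(y, x)
  expect_lt(abs(sum(r)), 1e-10)
  expect_lt(abs(sum(r * x)) / sqrt(sum(x^2) * sum(r^2)), 1e-8)
  # slope-zero case: residuals are just the centred response
  yc <- unname(resid(lm(rnorm(40) ~ x)))
  expect_equal(ols_residuals(yc, x), yc - mean(yc), tolerance = 1e-10)
  expect_error(ols_residuals(y, rep(1, 40)), "constant")
})

test_that("standardized partial beta equals the z-score-then-OLS oracle", {
  set.seed(14)
  # orthogonal design: beta_M_std equals the simple correlation with logM
  logM <- rnorm(30)
  logBc <- resid(lm(rnorm(30) ~ logM))
  g <- round(50 + 5 * logM + rnorm(30))
  expect_equal(std_partial_beta(g, logM, logBc),
               pearson_cor(g, logM)$r, tolerance = 1e-10)
  g2 <- round(50 + 5 * logBc + rnorm(30))
  expect_lt(abs(std_partial_beta(g2, logM, logBc)), 0.15)
  # correlated design: agree with scaling every variable first
  for (i in 1:20) {
    z <- rnorm(25); logM <- z + rnorm(25, 0, 0.3); logBc <- -z + rnorm(25, 0, 0.3)
    g <- round(50 + 3 * logM + 2 * logBc + rnorm(25))
    oracle <- unname(coef(lm(scale(g) ~ scale(logM) + scale(logBc)))[2])
    expect_equal(std_partial_beta(g, logM, logBc), oracle, tolerance = 1e-10)
  }
  expect_error(std_partial_beta(g, logM, logM), "collinear")
})

test_that("scan results obey internal identities", {
  cfg <- synthetic_config(n_categories = 60, class_mix = c(0.4, 0.2, 0.4),
                          seed = 15)
  sp <- generate_species(cfg)
  gen <- generate_function_matrix(sp, cfg)
  sc <- nogf_scan(gen$counts, sp, hierarchy = gen$hierarchy)
  res <- sc$results
  expect_equal(res$r2_simple, res$r_M^2, tolerance = 1e-12)
  expect_equal(res$r2_corrected, res$r_partial^2, tolerance = 1e-12)
  ok <- res$defined & abs(res$r_partial) > 1e-6
  expect_equal(sign(res$beta_M_std[ok]), sign(res$r_partial[ok]))
  expect_true(all(abs(res$r_M[res$defined]) <= 1))
  expect_true(all(res$p_M[res$defined] > 0 & res$p_M[res$defined] <= 1))
  expect_equal(res$upper_category_id, unname(gen$hierarchy[res$category_id]))
})

test_that("all-null scans are calibrated and flagged categories are retained", {
  cfg <- synthetic_config(n_categories = 342, class_mix = c(0, 0, 1), seed = 16)
  sp <- generate_species(cfg)
  gen <- generate_function_matrix(sp, cfg)
  counts <- gen$counts
  counts[, 1] <- 7L                      # constant-count category
  sc <- nogf_scan(counts, sp)
  expect_equal(sc$n_flagged, 1L)
  expect_false(sc$results$defined[1])
  expect_true(is.na(sc$results$r_M[1]))
  frac <- mean(sc$results$p_M < 0.05, na.rm = TRUE)
  half <- 2.576 * sqrt(0.05 * 0.95 / 341)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("the metabolic confound manufactures uncorrected associations only", {
  # Within one dataset all categories share the same species-level noise
  # draw, so the mean corrected correlation only concentrates across
  # replicate datasets; average over 10 of them.
  stats <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_categories = 200, class_mix = c(1, 0, 0),
                            seed = 600 + s)
    sp <- generate_species(cfg)
    gen <- generate_function_matrix(sp, cfg)
    res <- nogf_scan(gen$counts, sp)$results
    pos <- gen$truth$beta > 0.2
    c(r_M_pos = mean(res$r_M[pos]),
      r_partial = mean(res$r_partial),
      sig_u = mean(res$p_M < 0.05),
      sig_c = mean(res$p_partial < 0.05))
  }, numeric(4))
  avg <- rowMeans(stats)
  # positive-effect categories correlate strongly negatively with mass
  expect_lt(avg[["r_M_pos"]], -0.5)
  # but the B_c-corrected association is centred near zero
  expect_lt(abs(avg[["r_partial"]]), 0.1)
  expect_gt(avg[["sig_u"]], 5 * avg[["sig_c"]])
})

test_that("species mismatches are dropped with a warning; too few is an error", {
  cfg <- synthetic_config(seed = 18)
  sp <- generate_species(cfg)
  gen <- generate_function_matrix(sp, cfg)
  counts <- gen$counts[1:20, ]
  expect_warning(sc <- nogf_scan(counts, sp), "dropped")
  expect_equal(sc$n, 20L)
  expect_setequal(sc$dropped_species, sp$species_id[21:33])
  expect_error(suppressWarnings(nogf_scan(gen$counts[1:3, ], sp)),
               "fewer than 4")
})

test_that("optional BH adjustment appends monotone q-values", {
  cfg <- synthetic_config(n_categories = 50, seed = 19)
  sp <- generate_species(cfg)
  gen <- generate_function_matrix(sp, cfg)
  sc <- nogf_scan(gen$counts, sp, p_adjust = "BH")
  expect_true(all(c("q_M", "q_partial") %in% names(sc$results)))
  expect_true(all(sc$results$q_M >= sc$results$p_M - 1e-12))
})
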