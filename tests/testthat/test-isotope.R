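test_that("delta conversion matches the defining identities and a hand calculation", {
  expect_equal(compute_delta(37, 10000, 37 / 10000), 0)
  expect_equal(compute_delta(2 * 3677, 1e6, 0.003677), 1000)
  # direct substitution: r_meas = 37/10000 = 0.0037;
  # (0.0037/0.003677 - 1) * 1000 = (23/3677) * 1000
  expect_equal(compute_delta(37, 10000, 0.003677), 23 / 3677 * 1000,
               tolerance = 1e-12)
  expect_error(compute_delta(5, 0, 0.003677), "positive")
  expect_error(compute_delta(5, 100, -1), "r_standard")
  # pooled replicates aggregate by ratio of summed counts
  expect_equal(pool_counts_delta(c(10, 30), c(1000, 3000), 0.01),
               compute_delta(40, 4000, 0.01))
})

test_that("delta conversion is monotone in counts and standard ratio", {
  base <- compute_delta(40, 10000, 0.003677)
  expect_true(all(diff(compute_delta(40:60, 10000, 0.003677)) > 0))
  expect_true(all(diff(compute_delta(40, 10000, seq(0.002, 0.006,
                                                    by = 5e-4))) < 0))
  expect_gt(compute_delta(40, 9000, 0.003677), base)
})

test_that("HCE regression is exact on exact lines and zero on flat delta", {
  est <- fit_hce(make_spots(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(est$slope, 10)
  expect_equal(est$slope_se, 0)
  expect_equal(est$r_squared, 1)
  expect_true(est$enriched)

  flat <- fit_hce(make_spots(c(1, 2, 3, 4), c(7, 7, 7, 7)))
  expect_equal(flat$slope, 0)
  expect_false(flat$enriched)

  expect_error(fit_hce(make_spots(c(2, 2, 2), c(1, 2, 3))), "degenerate")
  expect_error(fit_hce(make_spots(c(1, 2), c(1, 2))), "insufficient")
})

test_that("2-SE slope intervals cover the true HCE at nominal rate", {
  set.seed(101)
  hits <- vapply(seq_len(1000), function(i) {
    fluor <- rlnorm(20, log(100), 0.5)
    est <- fit_hce(make_spots(fluor, 5 * fluor + rnorm(20, 0, 50)))
    abs(est$slope - 5) <= 2 * est$slope_se
  }, logical(1))
  # 2 SE ~ 95.9% for t with 18 df; allow Monte-Carlo slack downward
  expect_gte(mean(hits), 0.93)
})

test_that("HCE regression is equivariant under fluorescence scaling and delta shifts", {
  set.seed(7)
  fluor <- rlnorm(15, log(100), 0.5)
  delta <- 3 * fluor + rnorm(15, 0, 20)
  base <- fit_hce(make_spots(fluor, delta))
  scaled <- fit_hce(make_spots(10 * fluor, delta))
  expect_equal(scaled$slope, base$slope / 10, tolerance = 1e-10)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-10)
  shifted <- fit_hce(make_spots(fluor, delta + 500))
  expect_equal(shifted$slope, base$slope, tolerance = 1e-10)
  expect_equal(shifted$intercept, base$intercept + 500, tolerance = 1e-8)
  # duplicating every spot leaves the OLS slope unchanged
  doubled <- fit_hce(make_spots(rep(fluor, 2), rep(delta, 2)))
  expect_equal(doubled$slope, base$slope, tolerance = 1e-10)
})

test_that("enrichment decisions match the t distribution", {
  strong <- make_hces("a", "H", slope = 10, slope_se = 0.5)
  strong$n_spots <- 20L; strong$mean_delta <- 100
  strong$p_enrich <- NA_real_
  expect_true(flag_enrichment(strong, alpha = 0.05))

  zero <- strong; zero$slope <- 0
  expect_false(flag_enrichment(zero))

  # slope 2, SE 1, n 10: t = 2 on 8 df; the one-sided critical value is
  # 1.860 at alpha 0.05 (enriched) and 2.306 at alpha 0.025 (not)
  borderline <- strong
  borderline$slope <- 2; borderline$slope_se <- 1; borderline$n_spots <- 10L
  expect_true(flag_enrichment(borderline, alpha = 0.05))
  expect_false(flag_enrichment(borderline, alpha = 0.025))

  # positive-mean-delta requirement blocks slopes through negative deltas
  negmean <- strong; negmean$mean_delta <- -10
  expect_false(flag_enrichment(negmean))
  expect_true(flag_enrichment(negmean, require_positive_mean = FALSE))

  # degenerate SE = 0 with positive slope counts as enriched
  exact <- strong; exact$slope_se <- 0; exact$p_enrich <- NA_real_
  expect_true(flag_enrichment(exact))
})

test_that("fit_all_hce fits every cell and skips degenerate ones with a warning", {
  set.seed(5)
  spots <- rbind(make_taxon_spots(taxon = "a"),
                 make_taxon_spots(taxon = "b"))
  hces <- fit_all_hce(spots)
  expect_equal(nrow(hces), 6)
  expect_setequal(unique(hces$taxon), c("a", "b"))

  thin <- make_spots(c(1, 2), c(1, 2), taxon = "c")
  expect_warning(out <- fit_all_hce(rbind(spots, thin)), "skipped.*c/H")
  expect_equal(nrow(out), 6)
})
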