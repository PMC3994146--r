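test_that("activity ranking splits HIGH and LOW at the fraction-of-max cutoff", {
  hces <- make_hces(c("a", "b", "c"), "H", slope = c(10, 6, 1))
  res <- rank_activity(hces, cutoff_fraction = 0.5)
  expect_equal(res$cutoff, 5)
  expect_equal(res$classes$class[res$classes$taxon %in% c("a", "b")],
               c("HIGH", "HIGH"))
  expect_equal(res$classes$class[res$classes$taxon == "c"], "LOW")
  expect_equal(res$classes$rank, 1:3)

  same <- rank_activity(make_hces(c("a", "b"), "H", slope = c(4, 4)))
  expect_true(all(same$classes$class == "HIGH"))

  none <- make_hces("a", "H", slope = 1, enriched = FALSE)
  expect_warning(res0 <- rank_activity(none), "no enriched taxa")
  expect_equal(nrow(res0$classes), 0)
})

test_that("activity HIGH count matches an independent threshold scan on a lognormal sample", {
  set.seed(107)
  v <- rlnorm(107, 0, 1)
  hces <- make_hces(paste0("otu", 1:107), "H", slope = v)
  res <- rank_activity(hces, cutoff_fraction = 0.5)
  expect_equal(sum(res$classes$class == "HIGH"), sum(v >= 0.5 * max(v)))
  # percent-change series matches a direct recompute on the sorted values
  sv <- sort(v, decreasing = TRUE)
  expect_equal(res$classes$pct_change[1],
               100 * (sv[1] - sv[2]) / sv[2], tolerance = 1e-10)
})

test_that("ANCOVA finds no effect for exchangeable treatment groups", {
  fluor <- c(10, 20, 30, 40, 50)
  delta <- c(105, 195, 310, 395, 500)
  spots <- do.call(rbind, lapply(c("H", "M", "L"), function(t)
    make_spots(fluor, delta, treatment = t)))
  res <- ancova_concentration_effect(spots)
  expect_gt(res$p_value, 0.99)
  expect_false(res$partial)
})

test_that("ANCOVA detects clearly separated slopes with high power", {
  set.seed(42)
  hits <- vapply(seq_len(500), function(i) {
    spots <- make_taxon_spots(c(H = 10, M = 5, L = 1), n = 20, noise_sd = 1)
    ancova_concentration_effect(spots)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("two-treatment input yields a flagged partial result", {
  set.seed(3)
  spots <- make_taxon_spots(c(H = 10, M = 5, L = 1), n = 10)
  two <- spots[spots$treatment != "L", ]
  res <- ancova_concentration_effect(two)
  expect_true(res$partial)
  expect_lt(res$p_value, 0.05)
  one <- spots[spots$treatment == "H", ]
  expect_error(ancova_concentration_effect(one), ">= 2 treatment levels")
})

test_that("post-hoc pairs recover the separation structure", {
  set.seed(11)
  spots <- make_taxon_spots(c(H = 10, M = 5, L = 1), n = 20, noise_sd = 1)
  p <- ancova_concentration_effect(spots)$p_value
  ph <- posthoc_pairs(spots, p)
  expect_setequal(ph$significant, c("HM", "HL", "ML"))
  expect_length(ph$reversed, 0)

  set.seed(12)
  hm_equal <- make_taxon_spots(c(H = 10, M = 10, L = 1), n = 20,
                               noise_sd = 1)
  p2 <- ancova_concentration_effect(hm_equal)$p_value
  ph2 <- posthoc_pairs(hm_equal, p2)
  expect_setequal(ph2$significant, c("HL", "ML"))

  # the overall-p gate forces an empty set
  gated <- posthoc_pairs(spots, overall_p = 0.5)
  expect_length(gated$significant, 0)

  # a significant reversal (L incorporating more than H) is not "significant"
  # in the directed sense but recorded as reversed
  set.seed(13)
  rev_spots <- make_taxon_spots(c(H = 1, M = 5, L = 10), n = 20,
                                noise_sd = 1)
  p3 <- ancova_concentration_effect(rev_spots)$p_value
  ph3 <- posthoc_pairs(rev_spots, p3)
  expect_length(ph3$significant, 0)
  expect_setequal(ph3$reversed, c("HM", "HL", "ML"))
})

test_that("the guild decision table is total and matches the declared patterns", {
  mk <- function(sig, rev = character(0)) {
    list(significant = sig, reversed = rev)
  }
  expect_equal(classify_guild(0.5, mk(character(0))), "NULL_HML")
  expect_equal(classify_guild(0.01, mk(c("HM", "HL", "ML"))), "COPIOTROPH")
  expect_equal(classify_guild(0.01, mk(c("HM", "ML"))), "COPIOTROPH")
  expect_equal(classify_guild(0.01, mk(c("HL", "ML"))), "INTERMEDIATE")
  expect_equal(classify_guild(0.01, mk("ML")), "INTERMEDIATE")
  expect_equal(classify_guild(0.01, mk("HL")), "INTERMEDIATE")
  expect_equal(classify_guild(0.01, mk("HM")), "OTHER")
  expect_equal(classify_guild(0.01, mk(character(0))), "OTHER")
  expect_equal(classify_guild(0.01, mk("ML", rev = "HM")), "OTHER")
  expect_equal(classify_guild(NA_real_, mk("ML")), "OTHER")

  # totality: every subset of pairs, with and without a significant overall
  # test, maps to exactly one known label
  pairs <- c("HM", "HL", "ML")
  labels <- c("NULL_HML", "INTERMEDIATE", "COPIOTROPH", "OTHER")
  subsets <- unlist(lapply(0:3, function(k)
    combn(pairs, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    for (p in c(0.2, 0.001)) {
      g <- classify_guild(p, mk(s))
      expect_length(g, 1)
      expect_true(g %in% labels)
    }
  }
})

test_that("classify_taxa recovers known guilds on well-separated data", {
  set.seed(21)
  truth <- c(a = "COPIOTROPH", b = "INTERMEDIATE", c = "NULL_HML")
  slope_map <- list(COPIOTROPH = c(H = 10, M = 5, L = 1),
                    INTERMEDIATE = c(H = 10, M = 10, L = 2),
                    NULL_HML = c(H = 10, M = 10, L = 10))
  spots <- do.call(rbind, lapply(names(truth), function(tx)
    make_taxon_spots(slope_map[[truth[tx]]], n = 20, noise_sd = 1,
                     taxon = tx)))
  res <- classify_taxa(spots)
  expect_equal(setNames(res$guild, res$taxon), truth)
  tally <- guild_tally(res)
  expect_equal(tally$COPIOTROPH, 1L)
  expect_equal(tally$INTERMEDIATE, 1L)
  expect_equal(tally$NULL_HML, 1L)
  expect_equal(tally$n_taxa, 3L)
})
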