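test_that("parsimony scores match hand-checkable characters", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_score(tree, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(fitch_score(tree, c(A = 1, B = 1, C = 1, D = 1)), 0)
  tree2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(fitch_score(tree2, c(A = 1, B = 1, C = 0, D = 0)), 2)
  expect_error(fitch_score(tree, c(A = 1, B = 1, C = 0)), "without a")
  expect_equal(fitch_score(tree, c(A = 1, B = 1, C = 0, D = NA),
                           exclude_missing = TRUE), 1)
})

test_that("parsimony equals exhaustive minimization on all small binary trees", {
  skip_if_not_installed("phangorn")
  for (n in 4:6) {
    trees <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = LETTERS[1:n])
    chars <- as.matrix(expand.grid(rep(list(1:2), n)))
    for (ti in seq_along(trees)) {
      tree <- trees[[ti]]  # [[ ]] reattaches tip labels on multiPhylo
      for (r in seq_len(nrow(chars))) {
        states <- setNames(chars[r, ], LETTERS[1:n])
        # oracle matches tip order by label
        tip_states <- unname(states[tree$tip.label])
        expect_identical(fitch_score(tree, states),
                         brute_fitch(tree, tip_states, k = 2))
      }
    }
  }
})

test_that("parsimony handles multifurcations exactly", {
  # star tree: any 2-state character costs exactly (#minority state) changes
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  expect_equal(fitch_score(star, c(A = 1, B = 1, C = 0, D = 0, E = 0)), 2)
  expect_equal(fitch_score(star, c(A = 1, B = 0, C = 0, D = 0, E = 0)), 1)
  # random polytomous trees vs the exhaustive oracle
  set.seed(77)
  for (i in 1:20) {
    tree <- ape::di2multi(ape::rtree(7), tol = 0.4)
    states <- setNames(sample(1:3, 7, replace = TRUE), tree$tip.label)
    if (length(unique(states)) == 1) next
    expect_identical(fitch_score(tree, states),
                     brute_fitch(tree, unname(states[tree$tip.label]),
                                 k = 3))
  }
})

test_that("parsimony is invariant to rooting and tip order, and matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    tree <- ape::rtopology(n, rooted = FALSE)
    states <- setNames(sample(0:1, n, replace = TRUE,
                              prob = c(0.6, 0.4)), tree$tip.label)
    if (length(unique(states)) == 1) states[1] <- 1 - states[1]
    s <- fitch_score(tree, states)
    rooted <- ape::root(tree, outgroup = sample(tree$tip.label, 1),
                        resolve.root = TRUE)
    expect_identical(fitch_score(rooted, states), s)
    rot <- ape::rotateConstr(tree, sample(tree$tip.label))
    expect_identical(fitch_score(rot, states), s)
    dat <- phangorn::phyDat(matrix(states[tree$tip.label], ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = 0:1)
    expect_equal(s, as.integer(phangorn::parsimony(tree, dat)))
    # binary-character upper bound: no more changes than the minority count
    expect_lte(s, min(table(states)))
  }
})

test_that("tip-label reshuffling is seeded, bounded and count-preserving", {
  tree <- simulate_tree(24, rng_seed = 2)
  states <- setNames(rep(c(1L, 0L), c(8, 16)), tree$tip.label)
  a <- reshuffle_null(tree, states, n_reshuffles = 50, rng_seed = 99)
  b <- reshuffle_null(tree, states, n_reshuffles = 50, rng_seed = 99)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 8))
  const <- setNames(rep(1L, 24), tree$tip.label)
  expect_equal(reshuffle_null(tree, const, n_reshuffles = 1), 0L)
})

test_that("null mean agrees with an independent large-sample shuffle oracle", {
  skip_if_not_installed("phangorn")
  set.seed(321)
  tree <- ape::stree(32, type = "balanced")
  tree$tip.label <- paste0("t", 1:32)
  states <- setNames(rep(c(1L, 0L), c(8, 24)), tree$tip.label)
  null <- reshuffle_null(tree, states, n_reshuffles = 2000, rng_seed = 4)
  # oracle: independent resampling route through phangorn's Fitch
  oracle <- vapply(seq_len(2000), function(i) {
    shuffled <- sample(unname(states))
    dat <- phangorn::phyDat(matrix(shuffled, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = 0:1)
    as.integer(phangorn::parsimony(tree, dat))
  }, integer(1))
  se <- sqrt(var(null) / 2000 + var(oracle) / 2000)
  expect_lt(abs(mean(null) - mean(oracle)), 4 * se + 1e-9)
})

test_that("empirical and F-style p-values follow their definitions", {
  p <- signal_pvalues(2, rep(10, 1000))
  expect_equal(p$p_empirical, 1 / 1001)
  expect_true(is.na(p$p_ftest))  # zero-variance null

  null <- c(rep(5, 500), rep(9, 500))
  mid <- signal_pvalues(7, null)
  expect_equal(mid$p_empirical, 501 / 1001)

  set.seed(8)
  null2 <- rpois(1000, 10)
  obs <- round(median(null2))
  p2 <- signal_pvalues(obs, null2)
  expect_gt(p2$p_empirical, 0.3)
  expect_lt(p2$p_empirical, 0.8)
  # F statistic recomputed directly from its definition
  f <- (obs - mean(null2))^2 / var(null2)
  expect_equal(p2$p_ftest, pf(f, 1, 999, lower.tail = FALSE))
})

test_that("ancestral reconstructions achieve the parsimony minimum", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  const <- ancestral_states(tree, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(all(const$state == 1))
  expect_false(any(const$ambiguous))

  split <- ancestral_states(tree, c(A = 1, B = 1, C = 0, D = 0))
  implied <- sum(split$state[tree$edge[, 1]] != split$state[tree$edge[, 2]])
  expect_equal(implied, 1)

  set.seed(19)
  for (i in 1:30) {
    t6 <- ape::rtopology(6, rooted = FALSE)
    states <- setNames(sample(1:2, 6, replace = TRUE), t6$tip.label)
    if (length(unique(states)) == 1) next
    anc <- ancestral_states(t6, states)
    post <- ape::reorder.phylo(t6, "postorder")
    implied <- sum(anc$state[post$edge[, 1]] != anc$state[post$edge[, 2]])
    expect_equal(implied,
                 brute_fitch(t6, unname(states[t6$tip.label]), k = 2))
    # tips keep their observed states
    expect_equal(anc$state[seq_len(6)], unname(states[t6$tip.label]))
  }
})

test_that("per-guild signal testing skips degenerate guilds and excludes OTHER", {
  tree <- simulate_tree(12, rng_seed = 6)
  guilds <- data.frame(
    taxon = tree$tip.label,
    guild = c(rep("NULL_HML", 6), rep("INTERMEDIATE", 4), "OTHER", "OTHER"),
    stringsAsFactors = FALSE)
  cfg <- analysis_config(n_reshuffles = 50, rng_seed = 3)
  res <- phylo_signal_all(tree, guilds, cfg)
  expect_setequal(names(res$per_guild), c("NULL_HML", "INTERMEDIATE"))
  expect_setequal(res$excluded, tree$tip.label[11:12])

  mono <- guilds; mono$guild <- "NULL_HML"
  expect_warning(res2 <- phylo_signal_all(tree, mono, cfg),
                 "constant or < 2")
  expect_length(res2$per_guild, 0)
})

test_that("a clade-seeded character is detected, a shuffled one is not (power sanity)", {
  tree <- simulate_tree(50, rng_seed = 23)
  truth <- assign_guilds(tree, c(NULL_HML = 0.6, INTERMEDIATE = 0.4),
                         clustering_mode = "clade_seeded", rng_seed = 23)
  states <- setNames(as.integer(truth$guild == "INTERMEDIATE"), truth$taxon)
  sig <- phylo_signal(tree, states, n_reshuffles = 500, rng_seed = 1)
  expect_lt(sig$p_empirical, 0.05)
  expect_lte(sig$observed_score, 2)  # at most one change per seeded clade
})
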