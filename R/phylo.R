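#' Fitch parsimony score of a discrete character on a tree
#'
#' Minimum number of state changes required to explain the tip states, the
#' classic measure of how clustered a trait is on a phylogeny. The tree is
#' treated as unrooted (the score is invariant to rooting position); branch
#' lengths are ignored. Multifurcations are handled exactly via Hartigan's
#' generalization of the Fitch pass: an internal node keeps the states
#' present in the maximal number of its children's state sets and
#' contributes (number of children - that maximum) changes.
#'
#' @param tree an \code{ape::phylo}; leaves labelled by taxon id.
#' @param states named vector (names = tip labels) of discrete states; any
#'   atomic type, internally coded 1..k.
#' @param exclude_missing drop tips without a state instead of erroring.
#' @return integer score.
#' @export
fitch_score <- function(tree, states, exclude_missing = FALSE) {
  prep <- prepare_character(tree, states, exclude_missing)
  fitch_score_impl(prep$edge, prep$ntip, prep$k, prep$tip_states)
}

# Validates the (tree, states) pair and codes states as integers 1..k on a
# postorder edge table. Returns all pieces downstream passes need.
prepare_character <- function(tree, states, exclude_missing = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(states))) {
    stop("states must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(states))
  keep_na <- names(states)[is.na(states)]
  missing <- union(missing, intersect(keep_na, tree$tip.label))
  if (length(missing)) {
    if (!exclude_missing) {
      stop("tip(s) without a character state: ",
           paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) ", ..." else "", call. = FALSE)
    }
    if (length(tree$tip.label) - length(missing) < 2) {
      stop("fewer than 2 scored tips remain after exclusion", call. = FALSE)
    }
    tree <- ape::drop.tip(tree, missing)
  }
  states <- states[tree$tip.label]
  lev <- sort(unique(as.vector(states)))
  k <- length(lev)
  if (k < 1) stop("no states supplied", call. = FALSE)
  coded <- match(as.vector(states), lev)
  # a constant character still scores (0): code on k = 2 for the C pass
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, ntip = length(tree$tip.label),
       k = max(k, 2L), tip_states = as.integer(coded),
       levels = lev, tree = tree)
}

#' Tip-label reshuffling null distribution of the parsimony score
#'
#' Permutes the observed multiset of tip states uniformly at random across
#' the leaves (preserving state counts) and scores each permutation,
#' building the null distribution against which phylogenetic clustering is
#' judged: a clustered character needs fewer changes than its reshuffled
#' counterparts.
#'
#' @inheritParams fitch_score
#' @param n_reshuffles number of permutations (study default 1000).
#' @param rng_seed integer seed; same seed, same null scores.
#' @return integer vector of length \code{n_reshuffles}.
#' @export
reshuffle_null <- function(tree, states, n_reshuffles = 1000L,
                           rng_seed = 1L, exclude_missing = FALSE) {
  stopifnot(n_reshuffles >= 1)
  prep <- prepare_character(tree, states, exclude_missing)
  set.seed(rng_seed)
  perm <- vapply(seq_len(n_reshuffles),
                 function(i) sample(prep$tip_states),
                 integer(prep$ntip))
  fitch_scores_batch_impl(prep$edge, prep$ntip, prep$k, perm)
}

#' Significance of phylogenetic clustering from a permutation null
#'
#' The headline statistic is the one-sided empirical p-value
#' p = (1 + #\{null <= observed\}) / (1 + n): clustering means fewer changes
#' than expected under random tip assignment. A variance-ratio statistic
#' F = (observed - mean(null))^2 / var(null) on (1, n - 1) df is also
#' reported, mirroring the F-test the original analysis quoted against its
#' permutation null; it is two-sided in spirit and kept for fidelity, not
#' for the decision.
#'
#' @param observed observed parsimony score.
#' @param null_scores vector from \code{\link{reshuffle_null}}.
#' @return list: p_empirical, p_ftest (NA for a zero-variance null),
#'   null_mean, null_sd, n.
#' @export
signal_pvalues <- function(observed, null_scores) {
  stopifnot(length(null_scores) >= 1)
  n <- length(null_scores)
  p_emp <- (1 + sum(null_scores <= observed)) / (1 + n)
  v <- var(null_scores)
  p_f <- if (n >= 2 && is.finite(v) && v > 0) {
    pf((observed - mean(null_scores))^2 / v, 1, n - 1, lower.tail = FALSE)
  } else NA_real_
  list(p_empirical = p_emp, p_ftest = p_f,
       null_mean = mean(null_scores), null_sd = sd(null_scores), n = n)
}

#' One most-parsimonious ancestral-state assignment
#'
#' Up-pass (Hartigan state sets) followed by a down-pass that keeps the
#' parent's state whenever it lies in the child's set; nodes whose state set
#' holds more than one state are flagged ambiguous (other equally
#' parsimonious assignments exist there). The returned assignment achieves
#' the \code{\link{fitch_score}} minimum.
#'
#' @inheritParams fitch_score
#' @return data.frame: node (ape node id), state, ambiguous; tips included
#'   (never ambiguous).
#' @export
ancestral_states <- function(tree, states, exclude_missing = FALSE) {
  prep <- prepare_character(tree, states, exclude_missing)
  tree <- prep$tree
  edge <- prep$edge
  ntip <- prep$ntip
  k <- prep$k
  nnode <- max(edge)
  cnt <- matrix(0L, nnode, k)
  nchild <- integer(nnode)
  sets <- matrix(FALSE, nnode, k)
  sets[cbind(seq_len(ntip), prep$tip_states)] <- TRUE
  finalize <- function(node) {
    K <- max(cnt[node, ])
    sets[node, ] <<- cnt[node, ] == K
  }
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    if (ch > ntip) finalize(ch)
    cnt[p, ] <- cnt[p, ] + sets[ch, ]
    nchild[p] <- nchild[p] + 1L
  }
  root <- edge[nrow(edge), 1]
  finalize(root)
  # down-pass in preorder (reverse postorder edges)
  state <- integer(nnode)
  state[root] <- which(sets[root, ])[1]
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    state[ch] <- if (sets[ch, state[p]]) state[p] else which(sets[ch, ])[1]
  }
  lev <- prep$levels
  if (length(lev) < k) lev <- c(lev, rep(NA, k - length(lev)))
  data.frame(
    node = seq_len(nnode),
    label = c(tree$tip.label, rep(NA_character_, nnode - ntip)),
    state = lev[state],
    ambiguous = rowSums(sets) > 1,
    stringsAsFactors = FALSE
  )
}

#' Phylogenetic-signal test for one binary character
#'
#' @inheritParams reshuffle_null
#' @return list of class \code{chipsip_signal}: observed_score, null_scores,
#'   and the fields of \code{\link{signal_pvalues}}.
#' @export
phylo_signal <- function(tree, states, n_reshuffles = 1000L, rng_seed = 1L,
                         exclude_missing = FALSE) {
  obs <- fitch_score(tree, states, exclude_missing)
  null <- reshuffle_null(tree, states, n_reshuffles, rng_seed,
                         exclude_missing)
  out <- c(list(observed_score = obs, null_scores = null),
           signal_pvalues(obs, null))
  class(out) <- "chipsip_signal"
  out
}

#' Test every trophic guild for phylogenetic clustering
#'
#' For each guild label present among the assignments, membership is coded
#' as a binary tip character (member / non-member) and tested with
#' \code{\link{phylo_signal}} — one character per guild, matching the
#' per-strategy supplementary analysis. Taxa labelled OTHER and taxa absent
#' from the tree are excluded and reported; tips without an assignment are
#' dropped. Guilds with fewer than 2 members, or covering all scored tips
#' (constant character), are skipped with a warning. An optional joint test
#' treats the guild label itself as one k-state character.
#'
#' @param tree \code{ape::phylo}.
#' @param guilds assignments from \code{\link{classify_taxa}}.
#' @param config \code{\link{analysis_config}} (alpha, n_reshuffles, seed).
#' @param joint also run the k-state joint character test.
#' @return list: \code{per_guild} (named list of \code{chipsip_signal}),
#'   \code{joint} (or NULL), \code{excluded} (taxa not on the tree),
#'   \code{unassigned_tips}, \code{skipped} guilds.
#' @export
phylo_signal_all <- function(tree, guilds, config = analysis_config(),
                             joint = FALSE) {
  usable <- guilds[guilds$guild != "OTHER", , drop = FALSE]
  excluded_other <- setdiff(guilds$taxon, usable$taxon)
  on_tree <- usable$taxon %in% tree$tip.label
  excluded <- usable$taxon[!on_tree]
  usable <- usable[on_tree, , drop = FALSE]
  unassigned <- setdiff(tree$tip.label, usable$taxon)
  if (nrow(usable) < 3) {
    stop("fewer than 3 assignable taxa overlap the tree", call. = FALSE)
  }
  labels <- setNames(usable$guild, usable$taxon)
  per_guild <- list()
  skipped <- character(0)
  for (g in intersect(names(GUILDS), unique(usable$guild))) {
    member <- labels == g
    if (sum(member) < 2 || sum(!member) < 1) {
      skipped <- c(skipped, g)
      warning("guild ", g, " skipped (constant or < 2 members)",
              call. = FALSE)
      next
    }
    states <- setNames(ifelse(member, 1L, 0L), names(labels))
    per_guild[[g]] <- phylo_signal(tree, states, config$n_reshuffles,
                                   rng_seed = config$rng_seed +
                                     match(g, names(GUILDS)),
                                   exclude_missing = TRUE)
  }
  joint_res <- NULL
  if (joint && length(unique(labels)) >= 2) {
    joint_res <- phylo_signal(tree, labels, config$n_reshuffles,
                              rng_seed = config$rng_seed,
                              exclude_missing = TRUE)
  }
  list(per_guild = per_guild, joint = joint_res,
       excluded = c(excluded, excluded_other),
       unassigned_tips = unassigned, skipped = skipped)
}

#' Null-distribution histogram with the observed score marked
#'
#' @param signal a \code{chipsip_signal}.
#' @param path output file (.svg or .pdf).
#' @param main title (e.g. the guild label).
#' @return path, invisibly.
#' @export
plot_signal_histogram <- function(signal, path, main = "Parsimony null") {
  open_device(path, width = 6, height = 4.5)
  on.exit(grDevices::dev.off())
  null <- signal$null_scores
  breaks <- seq(min(c(null, signal$observed_score)) - 0.5,
                max(c(null, signal$observed_score)) + 0.5, by = 1)
  h <- graphics::hist(null, breaks = breaks, col = "grey80",
                      border = "white", main = main,
                      xlab = "parsimony score (state changes)")
  graphics::arrows(signal$observed_score, max(h$counts) * 0.5,
                   signal$observed_score, 0, length = 0.1, lwd = 2,
                   col = "firebrick")
  graphics::mtext(sprintf("observed = %d, p = %.4g", signal$observed_score,
                          signal$p_empirical), side = 3, cex = 0.8)
  invisible(path)
}

#' @export
print.chipsip_signal <- function(x, ...) {
  cat("Phylogenetic-signal permutation test\n")
  cat(sprintf("  observed parsimony score: %d\n", x$observed_score))
  cat(sprintf("  null: mean %.2f, sd %.2f (n = %d reshuffles)\n",
              x$null_mean, x$null_sd, x$n))
  cat(sprintf("  p_empirical = %.4g, p_ftest = %.4g\n",
              x$p_empirical, x$p_ftest))
  invisible(x)
}
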