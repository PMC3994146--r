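#' Default guild-to-slope mapping (permil per fluorescence unit)
#'
#' True HCE triplets (H, M, L) per guild. The concentration-saturated guild
#' (H~M~L) incorporates equally at all three additions; the intermediate
#' guild saturates only at the highest; the copiotroph-like guild increases
#' monotonically. Separations are large enough that recovery is a test of
#' the classifier, not of luck, and adjustable for power studies.
#'
#' @return named list of length-3 numeric vectors.
#' @export
default_guild_slopes <- function() {
  list(NULL_HML = c(H = 10, M = 10, L = 10),
       INTERMEDIATE = c(H = 10, M = 10, L = 2),
       COPIOTROPH = c(H = 10, M = 5, L = 1))
}

#' Simulate a random unrooted taxon tree
#'
#' Uniform random unrooted labelled topology (via \code{ape::rtopology});
#' stands in for the 16S phylogeny of the array's target taxa.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param rng_seed integer seed.
#' @param prefix tip-label prefix; labels are prefix1..prefixN.
#' @return \code{ape::phylo}, unrooted.
#' @export
simulate_tree <- function(n_taxa, rng_seed = 1L, prefix = "otu") {
  if (n_taxa < 3) stop("n_taxa must be >= 3", call. = FALSE)
  set.seed(rng_seed)
  tree <- ape::rtopology(n_taxa, rooted = FALSE)
  tree$tip.label <- paste0(prefix, seq_len(n_taxa))
  tree
}

#' Assign ground-truth guilds to the leaves of a tree
#'
#' In \code{random} mode labels are drawn i.i.d. with the given proportions
#' (no phylogenetic signal, the null of the clustering test). In
#' \code{clade_seeded} mode whole clades are filled with the non-majority
#' guilds — the clade nearest each target count is chosen — producing a
#' clustered character whose parsimony score is at most the number of seeded
#' clades; remaining leaves get the majority (first) guild.
#'
#' @param tree \code{ape::phylo}.
#' @param proportions named proportions over NULL_HML / INTERMEDIATE /
#'   COPIOTROPH summing to 1. Default mirrors the observed field tallies
#'   32:40:25.
#' @param clustering_mode "random" or "clade_seeded".
#' @param rng_seed integer seed.
#' @param slopes guild-to-HCE mapping, see \code{\link{default_guild_slopes}}.
#' @param n_probes probes per taxon (study arrays carried ~5-30 per set).
#' @param noise_sd Gaussian noise sd on delta, permil.
#' @return SyntheticTruth data.frame: taxon, guild, hce_H/M/L, n_probes,
#'   noise_sd, clustering_mode.
#' @export
assign_guilds <- function(tree,
                          proportions = c(NULL_HML = 32, INTERMEDIATE = 40,
                                          COPIOTROPH = 25) / 97,
                          clustering_mode = c("random", "clade_seeded"),
                          rng_seed = 1L,
                          slopes = default_guild_slopes(),
                          n_probes = 20L,
                          noise_sd = 50) {
  clustering_mode <- match.arg(clustering_mode)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            all(names(proportions) %in% names(GUILDS)))
  tips <- tree$tip.label
  n <- length(tips)
  set.seed(rng_seed)
  if (clustering_mode == "random") {
    guild <- sample(names(proportions), n, replace = TRUE,
                    prob = proportions)
  } else {
    guild <- seed_clades(tree, proportions)
  }
  truth <- data.frame(taxon = tips, guild = guild, stringsAsFactors = FALSE)
  hce <- t(vapply(guild, function(g) slopes[[g]], numeric(3)))
  truth$hce_H <- hce[, 1]; truth$hce_M <- hce[, 2]; truth$hce_L <- hce[, 3]
  truth$n_probes <- as.integer(n_probes)
  truth$noise_sd <- noise_sd
  truth$clustering_mode <- clustering_mode
  truth
}

# Fills whole clades with the minority guilds. Clades are tip sets below
# internal nodes of the (arbitrarily rooted) tree; for each guild after the
# first, the unused clade with size nearest the target count is taken.
seed_clades <- function(tree, proportions) {
  tips <- tree$tip.label
  n <- length(tips)
  targets <- round(proportions * n)
  post <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(post$edge)
  below <- vector("list", nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  clades <- below[(n + 1):nnode]
  guild <- rep(names(proportions)[1], n)
  used <- rep(FALSE, n)
  for (g in names(targets)[-1]) {
    want <- targets[[g]]
    if (want < 1) next
    free <- vapply(clades, function(cl) !any(used[cl]) &&
                     length(cl) < n - sum(used), logical(1))
    cand <- which(free)
    if (!length(cand)) {
      warning("no free clade left for guild ", g, "; left at majority label",
              call. = FALSE)
      next
    }
    sizes <- vapply(clades[cand], length, integer(1))
    pick <- cand[which.min(abs(sizes - want))]
    sel <- clades[[pick]]
    if (length(sel) != want) {
      message("guild ", g, ": nearest feasible clade has ", length(sel),
              " tips (target ", want, ")")
    }
    guild[sel] <- g
    used[sel] <- TRUE
  }
  guild
}

#' Simulate a Chip-SIP probe-spot table from ground truth
#'
#' Per taxon, \code{n_probes} probes get lognormal fluorescence shared across
#' the three treatments (the study labelled a combined RNA pool for
#' fluorescence, so one value per probe applies to H, M and L); each spot's
#' delta is true HCE x fluorescence plus Gaussian noise. The optional
#' heteroscedastic mode scales the noise sd with fluorescence relative to
#' the lognormal mean, bracketing counting-statistics behavior.
#'
#' @param truth SyntheticTruth from \code{\link{assign_guilds}}.
#' @param fluor_meanlog,fluor_sdlog lognormal fluorescence parameters
#'   (defaults log(100) and 0.5: scanner-scale positive intensities with a
#'   realistic right tail).
#' @param rng_seed integer seed.
#' @param heteroscedastic scale noise with fluorescence.
#' @return validated long-format probe table with columns probe, taxon,
#'   treatment, fluor, delta.
#' @export
simulate_probe_table <- function(truth, fluor_meanlog = log(100),
                                 fluor_sdlog = 0.5, rng_seed = 1L,
                                 heteroscedastic = FALSE) {
  stopifnot(all(truth$n_probes >= 3))
  if (any(truth$noise_sd < 0)) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  set.seed(rng_seed)
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tx <- truth[i, ]
    np <- tx$n_probes
    fluor <- rlnorm(np, fluor_meanlog, fluor_sdlog)
    slopes <- c(H = tx$hce_H, M = tx$hce_M, L = tx$hce_L)
    do.call(rbind, lapply(TREATMENTS, function(t) {
      sdv <- if (heteroscedastic) {
        tx$noise_sd * fluor / exp(fluor_meanlog + fluor_sdlog^2 / 2)
      } else rep(tx$noise_sd, np)
      data.frame(
        probe = paste0(tx$taxon, "_p", seq_len(np)),
        taxon = tx$taxon,
        treatment = t,
        fluor = fluor,
        delta = slopes[[t]] * fluor + rnorm(np, 0, sdv),
        stringsAsFactors = FALSE
      )
    }))
  })
  validate_probe_table(do.call(rbind, rows), context = "simulated table")
}

#' Simulate a complete Chip-SIP dataset with known ground truth
#'
#' Tree, guild labels and probe table, all derived from one master seed
#' (sub-seeds are small fixed offsets, so the whole dataset is reproducible
#' bit-for-bit). Defaults state the emulated world: 100 taxa, 20 probes per
#' taxon, guild proportions 32:40:25, slope triplets
#' (10,10,10)/(10,10,2)/(10,5,1) permil per fluorescence unit, and noise
#' sd 50 permil — calibrated so every true slope has slope/SE >= 5 at 20
#' probes.
#'
#' @param n_taxa number of taxa.
#' @param n_probes probes per taxon.
#' @param proportions guild proportions.
#' @param clustering_mode "random" or "clade_seeded".
#' @param noise_sd permil noise sd (0 allowed for noiseless checks).
#' @param slopes guild-to-slope mapping.
#' @param fluor_meanlog,fluor_sdlog lognormal fluorescence parameters.
#' @param heteroscedastic see \code{\link{simulate_probe_table}}.
#' @param rng_seed master seed.
#' @return list: tree, truth, spots.
#' @export
simulate_chipsip <- function(n_taxa = 100L, n_probes = 20L,
                             proportions = c(NULL_HML = 32,
                                             INTERMEDIATE = 40,
                                             COPIOTROPH = 25) / 97,
                             clustering_mode = "random",
                             noise_sd = 50,
                             slopes = default_guild_slopes(),
                             fluor_meanlog = log(100), fluor_sdlog = 0.5,
                             heteroscedastic = FALSE,
                             rng_seed = 1L) {
  rng_seed <- as.integer(rng_seed) %% 2147480000L
  tree <- simulate_tree(n_taxa, rng_seed = rng_seed)
  truth <- assign_guilds(tree, proportions, clustering_mode,
                         rng_seed = rng_seed + 1L, slopes = slopes,
                         n_probes = n_probes, noise_sd = noise_sd)
  spots <- simulate_probe_table(truth, fluor_meanlog, fluor_sdlog,
                                rng_seed = rng_seed + 2L,
                                heteroscedastic = heteroscedastic)
  list(tree = tree, truth = truth, spots = spots)
}

#' Write a simulated dataset to disk
#'
#' Probe table and truth as UTF-8 TSV, tree as Newick.
#'
#' @param sim list from \code{\link{simulate_chipsip}}.
#' @param dir output directory (created if needed).
#' @return named vector of the three paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(probes = file.path(dir, "probes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_probe_table(sim$spots, paths["probes"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  ape::write.tree(sim$tree, paths["tree"])
  invisible(paths)
}
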