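# Independent oracles and fixture builders shared across test files.

# Exhaustive minimum-change oracle: enumerate every internal-node state
# assignment and count changes over the edges. Exponential in the number of
# internal nodes; used only on small trees. Entirely independent of the
# package's Fitch/Hartigan pass.
brute_fitch <- function(tree, tip_states, k = max(tip_states)) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  full <- rbind(matrix(tip_states, nrow = ntip, ncol = nrow(grid)),
                t(grid))
  e <- tree$edge
  as.integer(min(colSums(full[e[, 1], , drop = FALSE] !=
                           full[e[, 2], , drop = FALSE])))
}

# Spots for one taxon/treatment with a known linear delta-fluorescence law.
make_spots <- function(fluor, delta, taxon = "tx", treatment = "H") {
  validate_probe_table(data.frame(
    probe = paste0("p", seq_along(fluor)),
    taxon = taxon, treatment = treatment,
    fluor = fluor, delta = delta,
    stringsAsFactors = FALSE
  ))
}

# One taxon's spots across all three treatments: shared lognormal
# fluorescence, per-treatment slopes, Gaussian noise.
make_taxon_spots <- function(slopes = c(H = 10, M = 5, L = 1),
                             n = 20, noise_sd = 1, taxon = "tx",
                             fluor = NULL) {
  if (is.null(fluor)) fluor <- rlnorm(n, log(100), 0.5)
  do.call(rbind, lapply(names(slopes), function(t) {
    make_spots(fluor, slopes[[t]] * fluor + rnorm(length(fluor), 0, noise_sd),
               taxon = taxon, treatment = t)
  }))
}

# Minimal HCE-estimate rows for classifier-level tests.
make_hces <- function(taxon, treatment, slope, enriched = TRUE,
                      slope_se = 0.1) {
  data.frame(taxon = taxon, treatment = treatment, slope = slope,
             slope_se = slope_se, intercept = 0, n_spots = 20L,
             r_squared = 0.9, mean_delta = pmax(slope, 0.1) * 100,
             p_enrich = ifelse(enriched, 1e-6, 0.5), enriched = enriched,
             stringsAsFactors = FALSE)
}
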