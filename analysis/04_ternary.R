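#!/usr/bin/env Rscript

# Step 4 — ternary composition of the three-concentration HCE profiles.
#
# Normalizes each enriched taxon's (HCE_H, HCE_M, HCE_L) to barycentric
# weights (negatives floored at zero) and renders the ternary diagram,
# colored by guild: copiotroph-like taxa pull toward the H corner,
# concentration-saturated taxa sit near the centroid.
#
# Reads:  results/hce.tsv, results/guilds.tsv
# Writes: results/ternary.tsv, results/ternary.svg

suppressPackageStartupMessages(library(chipsip))

hces <- read.delim("results/hce.tsv")
guilds <- read.delim("results/guilds.tsv")
pts <- ternary_coordinates(hces, guilds)
write.table(pts, "results/ternary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
render_ternary(pts, "results/ternary.svg")

cat(sprintf("placed %d enriched taxa on the simplex\n", nrow(pts)))
for (g in unique(pts$guild)) {
  cat(sprintf("  mean w_H for %-12s: %.3f\n", g,
              mean(pts$w_H[pts$guild == g])))
}
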