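# chipsip

Trophic-strategy analysis for Chip-SIP phylogenetic microarray experiments.

Chip-SIP measures which microbial taxa incorporate an isotope-labelled
substrate: rRNA from a labelled incubation is hybridized to a 16S
phylogenetic microarray and each probe spot is measured for fluorescence
(how much rRNA bound) and, by NanoSIMS, for its ¹⁵N/¹⁴N ratio (how much
label that rRNA carries). Ion counts become delta-permil enrichment via
δ = (R_meas/R_standard − 1) × 1000, and the per-taxon slope of δ on
fluorescence — the **hybridization-corrected enrichment (HCE)**, permil per
fluorescence unit — is a binding-corrected proxy for substrate incorporation.

Given probe-spot tables from incubations at three substrate concentrations
(H/M/L, e.g. 5 µM / 500 nM / 50 nM amino acids) and a tree of the target
taxa, the package:

1. fits HCE per taxon and treatment, with standard errors and a declared
   enrichment test (one-sided slope *t*-test + positive mean δ);
2. splits taxa into HIGH/LOW activity at a fraction-of-maximum HCE cutoff
   (default 50 %);
3. assigns trophic guilds by ANCOVA slope comparison across concentrations:
   H≈M≈L (saturated at the lowest addition, oligotroph-like), H≈M>L
   (intermediate), H>M>L (copiotroph-like), or OTHER;
4. normalizes each taxon's three HCEs to barycentric coordinates and draws
   the ternary diagram;
5. tests each guild for phylogenetic clustering: Fitch parsimony score of
   guild membership versus a 1000-fold tip-label reshuffling null, with
   parsimony ancestral states.

A synthetic-data generator with known ground truth (`simulate_chipsip()`)
makes every stage testable end to end.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a thin
driver over package functions and writes under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic world with known truth
Rscript analysis/02_fit_hce.R         # HCE regressions + activity ranking
Rscript analysis/03_classify_guilds.R # ANCOVA guild classification
Rscript analysis/04_ternary.R         # barycentric composition + plot
Rscript analysis/05_phylo_signal.R    # parsimony permutation tests
```

Output from a run (100 taxa, 20 probes each, guilds seeded into clades,
seed 20260918):

```
fitted 300 taxon/treatment HCEs; 300 of 300 enriched
    NULL_HML INTERMEDIATE   COPIOTROPH        OTHER
          29           41           28            2
guild recovery vs ground truth: 98.0%
  mean w_H for COPIOTROPH  : 0.624
  mean w_H for NULL_HML    : 0.332
Phylogenetic-signal permutation test
  observed parsimony score: 2
  null: mean 25.46, sd 1.80 (n = 1000 reshuffles)
  p_empirical = 0.000999, p_ftest = 4.723e-36
```

Read: 98 of 100 simulated taxa were assigned their true guild; the two
misassignments land in OTHER rather than a wrong guild. Copiotroph-like taxa
pull toward the H corner of the ternary plot (mean w_H 0.62 vs 0.33 for
saturated taxa). Guild membership needs only 2 state changes on the tree
against a null mean of ~25, so clustering is detected at the permutation
floor p = 1/1001.

The same entry point runs on real data:

```r
library(chipsip)
run <- run_pipeline("probes.tsv", "tree.nwk", analysis_config())
print(run)            # guild tallies, activity count, per-guild signal
run$results           # per-taxon table: HCE ± SE, flags, guild, w_H/w_M/w_L
```

Foreign column headers are remapped with
`read_probe_table(..., columns = probe_columns(taxon = "OTU_ID", ...))`;
tables carrying raw ¹²C¹⁴N⁻/¹²C¹⁵N⁻ ion counts instead of δ are converted by
passing `r_standard` to `run_pipeline()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch against the installed package:
it simulates the default synthetic world under the given seed, runs every
pipeline stage (HCE → enrichment → activity → ANCOVA guilds → ternary →
phylogenetic signal), prints the run summary and guild-recovery rate, and
writes the JSON report to `--out` (with full per-taxon outputs next to it
under `acceptance_run/`).
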