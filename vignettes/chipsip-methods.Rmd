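---
title: "Chip-SIP trophic-strategy analysis: models, parameters and design choices"
author: "chipsip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chip-SIP trophic-strategy analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipsip)
```

## The measurement and the model

Chip-SIP couples stable isotope probing with a phylogenetic microarray.
A water sample is incubated with a ^15^N-labelled substrate at several
concentrations; community rRNA is hybridized to taxon-specific probe sets,
and every probe spot is measured twice — once for fluorescence on a scanner
(how much rRNA bound) and once on a NanoSIMS for its ^15^N/^14^N secondary-ion
ratio (how much label that rRNA carries). Ion counts become relative
enrichment through the standard delta transform,

$$\delta = \left(\frac{R_{meas}}{R_{standard}} - 1\right) \times 1000\ \text{‰},$$

with $R_{standard}$ measured on unhybridized regions of the same array
(`compute_delta()`). When replicate count pairs must be aggregated first,
`pool_counts_delta()` uses the ratio of summed counts rather than the mean of
ratios: ion counts are Poisson, and the pooled ratio is the stable estimator.

A spot with more bound rRNA carries more label, so raw $\delta$ confounds
activity with probe binding. The quantity of interest is the
**hybridization-corrected enrichment (HCE)**: the ordinary-least-squares slope
of $\delta$ on fluorescence across one taxon's probe set, in permil per
fluorescence unit (`fit_hce()`). Its OLS standard error drives both the
two-standard-error error-bar convention and the enrichment decision. Because
fluorescence was measured on a combined labelling of all treatments, one
fluorescence value per probe is applied to all three concentrations; tables
with per-treatment fluorescence are accepted as-is.

### Enrichment rule

The original study excluded taxa that were "not significantly enriched"
without stating the criterion. The declared rule here (`flag_enrichment()`)
is: one-sided $t$-test of slope $> 0$ with $t = \hat\beta/\mathrm{SE}$ on
$n-2$ df at $\alpha$ (default 0.05), **and** mean $\delta > 0$, so a steep
slope fitted through background-level values cannot qualify. Both thresholds
are configurable; an exact fit (SE $= 0$) with positive slope counts as
enriched.

## Two classifications

**Activity.** Taxa are ranked by HCE at one reference concentration (default
H). A taxon is HIGH when its HCE is at least `activity_cutoff_fraction`
(default 0.5) of the maximum among enriched taxa; the percent change between
successive ranked values is returned so the cutoff can be inspected against
the shape of the distribution, which in the original data was lognormal with
a local high in percent change near 50 % of the maximum.

**Trophic guild.** For each taxon, an ANCOVA asks whether concentration
affects the fluorescence–enrichment relationship. The default model is the
full interaction $\delta \sim \text{fluor} \times \text{treatment}$, tested
against $\delta \sim \text{fluor}$ with a joint partial $F$-test — one
declared test that captures both a shifted intercept and a changed slope.
The simpler common-slope ANCOVA is available via
`analysis_config(ancova_model = "intercept")`. Degenerate fits are decided by
the relative RSS drop: if the treatment terms explain (numerically) nothing,
$p = 1$; if the full model is exact while the reduced one is not, $p = 0$ —
this keeps noiseless data on the decision table instead of producing NaN.

Significant taxa go to directed post-hoc pairwise ANCOVAs for (H,M), (H,L),
(M,L). A pair counts only when its $p$ clears $\alpha$ **and** the
higher-concentration HCE exceeds the lower one, since less substrate should
not drive more incorporation; a significant reversal is recorded and routes
the taxon to OTHER. The decision table (`classify_guild()`):

| condition | guild |
|---|---|
| overall $p \ge \alpha$ | `NULL_HML` (H≈M≈L, saturated at the lowest addition) |
| (H,M) and (M,L) significant | `COPIOTROPH` (H>M>L, never saturated) |
| (M,L) or (H,L) significant, (H,M) not | `INTERMEDIATE` (H≈M>L) |
| anything else | `OTHER` |

`OTHER` absorbs patterns the three-guild taxonomy cannot express — (H,M)
alone (a H>M≈L response, unobserved in the original data) and direction
violations — so the map is total; such taxa are reported but excluded from
guild counts and from the phylogenetic characters. Post-hoc $p$-values are
uncorrected by default, matching the apparent original procedure; Holm
adjustment is one switch away (`posthoc_adjust = "holm"`). Whether the
original post-hoc was pairwise ANCOVA, model contrasts or Tukey-style is not
recoverable; pairwise ANCOVA was chosen because it reuses the declared
overall test verbatim on two groups, and the decision table is agnostic to
which is slotted in.

## Ternary composition

Each enriched taxon's triplet $(\mathrm{HCE}_H, \mathrm{HCE}_M,
\mathrm{HCE}_L)$ is normalized to its sum and plotted in barycentric
coordinates. Negative HCEs — possible from noise around zero — are floored at
zero before normalizing, because barycentric weights must be nonnegative;
whether the original figure used signed or floored values is unstated, and
flooring is the choice that keeps every enriched taxon plottable. Taxa with
no positive component are excluded with a warning. Orientation is fixed (H
apex, M bottom-left, L bottom-right) so layouts are deterministic; the
Cartesian transform is $x = w_L + w_H/2$, $y = (\sqrt3/2)\,w_H$.

## Phylogenetic signal

Guild membership is coded as one binary character per guild on the 16S tree
(matching the per-strategy supplementary analysis; a $k$-state joint test is
available with `phylo_signal_all(..., joint = TRUE)`). The statistic is the
minimum number of state changes — the Fitch parsimony score — computed by a
postorder pass that treats the tree as unrooted and ignores branch lengths.
Multifurcations are handled exactly with Hartigan's generalization: a node
keeps the states present in the maximal number of its children's sets and
contributes (children − max count) changes; on binary trees this is exactly
Fitch. The pass is implemented in C++ so the permutation null is cheap.

The null reshuffles tip labels uniformly (preserving state counts) 1000
times by default. The headline decision uses the one-sided empirical
p-value $p = (1 + \#\{\text{null} \le \text{obs}\})/(1 + n)$ — clustering
means fewer changes than the null. The original analysis quoted an "F-Test"
against this null; its exact construction (Mesquite output) is not
recoverable, so a variance-ratio statistic
$F = (\text{obs} - \bar{\text{null}})^2/\mathrm{var}(\text{null})$ on
$(1, n-1)$ df is reported as `p_ftest` for fidelity, and is `NA` on a
zero-variance null. Ancestral states come from the Hartigan down-pass; nodes
with more than one equally parsimonious state are flagged ambiguous.

## The synthetic world

`simulate_chipsip()` generates datasets with known truth. Defaults state the
emulated conditions once: 100 taxa, 20 probes per taxon (field arrays
carried roughly 5–30 per set), lognormal fluorescence
($\mu_{\log} = \log 100$, $\sigma_{\log} = 0.5$ — positive scanner-scale
intensities with a realistic right tail) shared across treatments, guild
proportions 32:40:25 matching the field tallies, slope triplets
$(10,10,10)/(10,10,2)/(10,5,1)$ permil·fluor⁻¹, and homoscedastic Gaussian
noise with sd 50 ‰ on $\delta$, which puts slope/SE at about 5 for the
weakest true slope — strong but honest signal. A
fluorescence-proportional heteroscedastic mode brackets counting-statistics
behaviour. Guilds are assigned i.i.d. (`random`) or by filling whole clades
(`clade_seeded`), giving characters with no signal or strong signal
respectively. Everything derives from one master seed.

What the generator does **not** emulate: cross-hybridization between probe
sets, the lognormal spread of *activity* across taxa (all guilds share the
same H-concentration slope, so the HIGH/LOW split is exercised on lognormal
samples in the unit tests instead), NanoSIMS dead-time/QSA artefacts, and
probe-level fixed effects. A green recovery test therefore establishes that
the ANCOVA decision table and the signal test behave correctly under the
assumed linear-with-Gaussian-noise world, not that the laboratory pipeline
upstream of the spot table is sound.

## Numerical and interface choices

* Treatments are an ordered categorical H > M > L everywhere; inputs with
  other codes fail validation with row numbers.
* Minimum spots per regression: 3 (slope SE needs a residual df); cells
  below it are skipped and named in a warning, not silently dropped.
* Readers are total: a malformed table yields a diagnosed error, never a
  partial result. Column names are remappable (`probe_columns()`), so
  converted external matrices (e.g. a GEO deposit) can be adapted without
  editing files.
* Configuration is an in-R validated list serialized as JSON
  (`write_config()` / `read_config()`).
* Tabular outputs are UTF-8 TSV; plots are SVG with a PDF fallback where no
  cairo device exists.
* Taxa absent from the tree, and tips without assignments, are excluded
  from characters and reported in the run output rather than imputed.

## Limitations

Three concentrations cap the resolvable response patterns at the three
guilds plus OTHER; no kinetic constants are inferred. The permutation
p-value is bounded below by $1/(n+1)$. The activity cutoff is a descriptive
split of a continuum, not an inference. Reanalysis of the original deposit
requires converting its supplementary matrices to the probe-table schema;
the package ships no downloader.
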