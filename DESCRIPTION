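Package: chipsip
Title: Trophic-Strategy Analysis for Chip-SIP Phylogenetic Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for chip-based stable isotope probing
    (Chip-SIP) experiments, in which isotope-labeled rRNA hybridized to a
    phylogenetic microarray is measured spot-by-spot for fluorescence and
    NanoSIMS isotope ratios. Converts raw ion counts to delta-permil
    enrichment, estimates per-taxon hybridization-corrected enrichment (HCE)
    by regression of enrichment on probe fluorescence, classifies taxa into
    activity classes and substrate-concentration trophic guilds by ANCOVA
    slope comparison, maps normalized HCE triplets onto barycentric ternary
    coordinates, and tests each guild for phylogenetic clustering with a
    Fitch parsimony score against a tip-label permutation null. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
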