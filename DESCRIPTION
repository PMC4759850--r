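Package: uceclock
Title: Distance-Based Strict-Clock Divergence Dating for Ultraconserved Element Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-locus divergence-time estimation for ultraconserved element
    (UCE) alignments under a naive strict molecular clock. Time to most recent
    common ancestor (TMRCA) of a clade is estimated per locus from corrected
    pairwise Hamming distances between its daughter lineages, scaled against a
    calibrated split; calibrations cascade from a single root age down the
    tree, loci whose implied age exceeds their calibration are discarded as
    non-clock-like, and per-clade summaries report quartile spreads, locus
    status fractions, and lineage rate-shift calls from outgroup
    triangulation. Includes a synthetic UCE data generator (dated species
    tree, optional multispecies-coalescent gene-tree discordance, clock-like
    or rate-shifted sequence evolution, and empirically calibrated
    missing-data injection) so the whole pipeline can be exercised and
    validated against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
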