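Package: rtgloh
Title: Loss-of-Heterozygosity Analysis for Return-to-Growth Yeast Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses loss-of-heterozygosity (LOH) produced by
    return-to-growth (RTG) in diploid yeast hybrids. Provides a
    mechanism-based simulator of RTG mother/daughter genotype pairs
    (hotspot-weighted double-strand breaks resolved as crossovers or gene
    conversions with mitotic-like 2:2 chromatid segregation), a marker-based
    LOH caller with interstitial/terminal classification and dual coordinate
    systems, permutation tests for association between LOH breakpoints and
    meiotic recombination hotspots (with local shift Z-profiles and relative
    hotspot intensity comparisons), URA3-loss LOH rate metrics from colony
    counts, and single-marker LOD linkage mapping of growth phenotypes with
    permutation-derived genome-wide thresholds and LOD-drop support
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
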