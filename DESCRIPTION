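Package: codiv
Title: Community Co-Diversification Analysis from Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for testing whether the members of an
    ecological community share population genetic structure with a host
    across a biogeographic barrier. Takes demultiplexed amplicon reads
    (FASTA) plus a sample-to-locale-to-region table, trims and
    dereplicates reads, clusters them into OTUs by greedy abundance-sorted
    identity clustering with a chimera screen, aligns each OTU, and
    computes per-OTU diversity and structure statistics: nucleotide
    diversity, Watterson's theta, Tajima's D with a beta-distribution
    null, haplotype G_ST, hierarchical AMOVA Phi-statistics with
    scheme-specific permutation nulls, the genealogical sorting index on
    neighbor-joining trees, and Mantel tests of isolation by distance.
    Per-OTU significance calls are synthesised into a community-level
    chi-squared goodness-of-fit test of shared structure. A structured
    coalescent simulator generates barrier-split communities with known
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
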