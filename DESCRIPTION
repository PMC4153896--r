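Package: mitoqfp
Title: G-Quadruplex and Repeat Motif Association with Deletion Breakpoints
    on Circular Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans circular genomes (such as human mitochondrial DNA) for
    sequences with G-quadruplex forming potential (2G/3G intrastrand and
    duplex-derived interstrand motifs) and for exact fixed-length repeats of
    four orientation classes (direct, inverted, complementary, inverted
    complementary), reduces motifs to non-overlapping midpoint sets, and
    tests their association with deletion breakpoints using reciprocal
    Minimal Distance Analysis against exhaustive 1-nt rotational controls,
    per-distance binomial enrichment, and both-ends deletion proximity
    tests.  Includes generators for strand-asymmetric synthetic genomes,
    planted motifs, and simulated deletion sets for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
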