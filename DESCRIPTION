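Package: quadscan
Title: G-Quadruplex and i-Motif Discovery in Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative G-quadruplex-forming sequences (PQS) and
    i-motifs in assembled transcripts using the classical G3+ L1-7 tract/loop
    pattern, with both standard non-overlapping regex semantics and an
    exhaustive overlap-aware enumeration. Localizes hits to 5' UTR, CDS or
    3' UTR via longest-ORF annotation, applies the stringent raw-read removal
    rules used in de novo transcriptome studies (adapter match, ambiguous-base
    fraction, low-quality fraction), computes assembly summary statistics
    (N50, length distribution), and ships a synthetic-data generator that
    plants motifs and filter-rule violations with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    S4Vectors,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
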