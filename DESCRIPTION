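Package: karyoconvert
Title: Convert ISCN Karyotypes to Genomic Gain/Loss Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses human karyotypes written in ISCN cytogenetic nomenclature
    and reports the net chromosomal gains and losses they imply as genomic
    coordinate intervals, per clone and with cell counts when provided.
    Includes vendored UCSC cytoband tables for hg18, hg19 and GRCh38, a
    batch table converter, a genome-wide gain/loss heatmap, and a synthetic
    karyotype generator with a constructive copy-number oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
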