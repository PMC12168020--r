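Package: promotune
Title: Design and QC of Scarless CRISPR Promoter-Replacement Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of scarless CRISPR promoter-replacement
    constructs for yeast gene-expression tuning: sgRNA selection within the
    promoter window, SapI-free homology-arm extraction, assembly of the
    fixed-layout synthetic gene block, in silico SapI Golden Gate simulation
    of the single-pot promoter-insertion library, long-read library QC
    (coverage, coverage rate, abundance) via diagnostic tag matching, and
    screening statistics (normalized betanin absorbance, maximum specific
    growth rate). Ships deterministic toy-genome, read and plate simulators
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
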