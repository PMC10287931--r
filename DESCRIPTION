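Package: larpmap
Title: PAR-CLIP Binding-Site Calling and Ribosome-Footprint Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conversion-aware PAR-CLIP binding-site calling (kernel-density
    signal versus background with mode locations), transcript-region target
    annotation, CLIP enrichment and translation-efficiency quantification,
    ORF-centile and mode-centered metagene profiles for monosome, short and
    disome ribosome footprints, degenerate-motif reading-frame analysis,
    PARS secondary-structure windows, and dual-luciferase / qPCR reporter
    arithmetic. Includes a seeded synthetic-data generator with planted
    ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
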