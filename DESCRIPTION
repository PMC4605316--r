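Package: rsrnakit
Title: Discovery and Multi-Layer Validation of Regulatory Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a multi-stage discovery
    cascade for non-canonical regulatory small RNAs (rsRNAs) from pooled
    small-RNA sequencing: unique-read collapsing and abundance/recurrence
    filtering, dual-predictor target-site consensus (seed match plus
    near-complementary duplex), interaction validation against Argonaute
    CLIP peaks and CLASH chimeric reads, biogenesis-dependence
    classification from knockdown/CLIP read sets, hairpin and
    Microprocessor motif analysis (CNNC, basal UG, apical UGU),
    expression anti-correlation screening, and genomic/repeat annotation
    with consensus meta-profiles. Ships a deterministic synthetic-data
    generator with a ground-truth ledger so the whole cascade can be
    exercised and validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
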