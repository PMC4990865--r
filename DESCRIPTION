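Package: sfptools
Title: Identification of Seminal Fluid Proteins from Replicated Tissue Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evidence-integration pipeline for identifying seminal fluid
    proteins (SFPs) from label-free proteomic detection of male accessory
    gland (MAG) and female reproductive tract (FRT) samples. Peptide-spectrum
    matches are filtered at a target-decoy false discovery rate, collapsed to
    per-sample protein presence, and passed through a replicate-consistency
    filter. Candidate proteins detected in both MAG and mated-FRT samples are
    then classified as predicted-secreted SFPs (signal peptide, or
    male-specific expression combined with absence from unmated females),
    unconfirmed SFPs (cross-species homology to known insect SFPs), or
    unclassified candidates. Supporting modules provide RPKM expression
    normalization with expressed/male-specific flags, keyword-based functional
    categorisation, cross-species Domain/Blast marking, expression-share
    summaries, and a synthetic-data generator with planted ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
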