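Package: proteoforma
Title: Proteoform Identification, Quantification and Variant Filtering for
    Top-Down Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-identification analysis for deep top-down proteomics
    comparisons of two cell states. Merges proteoform-spectrum matches
    (PrSMs) across runs, applies two-tier target-decoy false discovery
    rate control (spectrum level, then proteoform level on cluster
    representatives), clusters PrSMs into proteoforms within a precursor
    mass window, builds label-free quantification matrices with
    fraction summation and median-ratio normalization, tests for
    differential proteoform abundance with an S0-moderated statistic and
    permutation-based FDR, profiles proteoform overlap, post-translational
    modification mass shifts and proteoform families, and filters single
    amino acid variant (SAAV) proteoforms by flanking fragment-ion
    evidence. Includes a seeded synthetic-data generator with known ground
    truth so that every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
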