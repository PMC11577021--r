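Package: ciberscreen
Title: Scoring of gRNA-Barcoded Extracellular Vesicle Release Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPR knockout screens that read out
    small extracellular vesicle (sEV) release through gRNA barcodes loaded into
    vesicles by a marker-dCas9 fusion (CIBER screening). Covers spacer counting
    from raw reads by scaffold-key anchoring, normalized read counts and
    abundance filters, the release-effect statistic (residuals from a two-pass
    trimmed regression of sEV on cellular fold changes), gene-level z-normalized
    release-effect (z-RE) scores and hit calls, cross-marker screen comparison,
    a TF-IDF contrast of enriched-term lists, and a synthetic-screen generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
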