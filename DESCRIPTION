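Package: zurscan
Title: Comparative Reconstruction of Bacterial Zur Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of the regulon of the zinc-uptake regulator (Zur)
    in actinobacterial genomes: palindromic positional-weight-matrix motif
    models with Z-score scoring, Gibbs-style motif discovery in orthologous
    upstream regions, genome scanning with cross-genome consistency-check
    filtering and operon expansion, two-colour microarray m/a analysis with
    LOWESS normalization and replicate-significance filtering, qPCR
    crossing-point fold changes, regulatory-geometry checks against mapped
    promoters, EMSA probe design, and a seeded synthetic genome-panel
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
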