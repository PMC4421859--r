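Package: metabofun
Title: Functional Gene Content, Mass-Specific Metabolic Rate, and Lifespan
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative analyses linking the proportion of genes in
    functional categories -- in particular genes of oxygen-requiring
    ("oxic") metabolic reactions -- to mass-specific metabolic rate and
    maximal lifespan across organisms from prokaryotes to mammals.
    Provides readers for KEGG-style annotation files (KGML pathway XML,
    BRITE keg hierarchies, nucleotide FASTA), per-genome functional
    profiling, temperature correction of metabolic rates (Q10-style and
    Boltzmann-Arrhenius), simple and body-mass-controlled partial Spearman
    rank correlation screens, allometric scaling-exponent estimation, and
    a synthetic organism-panel generator with planted effects for method
    validation.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
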