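Package: tmdcover
Title: Transmembrane-Domain Coverage Analysis for Bottom-Up Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a bottom-up proteomics experiment covers the
    membrane-spanning segments of transmembrane proteins. Provides in-silico
    chemical and enzymatic digestion (trypsin/Lys-C and cyanogen bromide with
    methionine-to-homoserine conversion), Kyte-Doolittle GRAVY hydropathy
    scoring, parsing of TMHMM topology predictions, peptide-to-protein mapping
    with containment/overlap classification of peptides against predicted
    transmembrane helices, parsimony-style protein grouping, and the comparison
    statistics (TMD-count histograms, chi-square goodness of fit, per-bin
    t-tests, replicate reproducibility, binomial category enrichment) used to
    contrast membrane-protein sample-preparation workflows. A seeded synthetic
    proteome and peptide-detection simulator makes every stage runnable and
    testable offline.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
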