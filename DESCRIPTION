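Package: herbarcode
Title: DNA Barcode Authentication of Herbal Materials Against an Adulterant Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and applying pharmacopoeia-style DNA barcode
    quality standards for medicinal plants, using Hypericum perforatum
    (St John's Wort) and its adulterant panel as the worked case study.
    Covers curation of panel sequence databases (outlier filtering, IUPAC
    consensus and subtype construction, discriminating-site and hotspot
    detection), reference-barcode matching with essential-base semantics and
    an overall identity threshold, chloroplast rbcL haplotype assignment from
    a coordinate-mapped SNP key, psbA-trnH stem-loop folding and long/short
    classification, compensatory base change (CBC) counting on ITS2 secondary
    structures, a multi-locus verdict engine producing M/m/P/p/U
    identification codes, and a synthetic-data generator that emulates the
    panel structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
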