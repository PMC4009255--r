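Package: markermine
Title: Mining Disease-Biomarker Associations from Literature Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A knowledge-driven text-mining toolkit for building disease-related
    biomarker knowledge bases from literature abstracts. Provides curation and
    variant expansion of gene and disease dictionaries, dictionary-based named
    entity recognition with leftmost-longest matching and concept
    normalization, biomarker trigger-term filtering, sentence-level
    disease-gene co-occurrence extraction, and section-weighted inverse
    document frequency scoring of candidate associations. Includes readers for
    PubMed XML, MEDLINE nbib and tabular corpora, bibliometric summaries, a
    synthetic fixture generator with ground truth for end-to-end validation,
    and a reproducible pipeline driver.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
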