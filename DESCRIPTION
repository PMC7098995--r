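Package: its2auth
Title: Subspecies-Level Authentication of Kudzu Products by ITS2 Barcoding and Metabarcoding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to authenticate raw materials, foods and herbal products
    derived from Pueraria montana var. lobata (kudzu, Gegen) and
    P. montana var. thomsonii (Fenge) at the subspecies level using the ITS2
    nuclear ribosomal marker. Implements a local reference database with
    diagnostic-site detection and weighted subspecies calling, Kimura
    2-parameter distances with barcoding-gap statistics, neighbor-joining
    trees with bootstrap support, a Sanger chromatogram model with
    heterozygous-peak base calling and trace purity classification, and a
    single-end amplicon metabarcoding pipeline (tag demultiplexing, quality
    filtering, anchor-based ITS2 trimming, dereplication and taxonomic
    assignment). A synthetic-data module generates reference sets, tagged
    FASTQ read batches, mixture chromatograms and study-scale sample panels
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
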