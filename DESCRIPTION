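Package: exoncnv
Title: Exon-Resolution Copy Number Variant Filtering and Visualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for exon-resolution copy number variant (CNV)
    analysis of CNVkit-style coverage tables. Parses per-bin (cnr), per-bin
    test (bintest) and per-segment (cns) tables, builds cohort exon-level
    frequency references with MLPA-like boxplot statistics, applies preset
    and custom CNV filters including consecutive-exon run detection and a
    Benjamini-Hochberg corrected bin-wise z-test, joins trios for de novo
    CNV candidates, computes B-allele-frequency series with a windowed
    loss-of-heterozygosity flag, reduces AnnotSV annotation tables, and
    ships a seeded synthetic-data generator plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
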