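Package: altiscan
Title: Two-Population Selection Scans and Nucleotide Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting a pair of populations (for example
    high-altitude versus low-altitude demes of a soil invertebrate) with
    variant-level data: hard-quality and minor-allele-count filtering of
    multi-sample VCFs, per-site Weir-Cockerham fixation-index variance
    components, per-site and per-gene nucleotide diversity, alignment-based
    estimators (segregating sites, Watterson's theta, pi, Tajima's D) and
    windowed Tajima's D, and a gene-level outlier scan that flags candidate
    genes jointly in the top decile of differentiation and of the
    -log10 diversity ratio. A Balding-Nichols two-population simulator
    generates VCF/BED/population-table/truth-table file sets so every stage
    of the pipeline can be exercised and calibrated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
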