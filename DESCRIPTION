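Package: partchar
Title: High-Throughput DNA Part Characterization from Colony Images and
    Tagged Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of DNA parts (promoters and
    ribosome-binding sites) from dual-channel fluorescent plate images and
    pooled barcode-tagged long-read sequencing. Detects and links colonies
    across GFP and RFP channel images and computes the ratiometric colony
    intensity, designs minimum-distance 7 bp tag sets and demultiplexes
    reads by forward/reverse tag combinations, calls per-colony genotypes
    by multi-reference local alignment with query-coverage filtering and
    purity quality scores, profiles combinatorial Golden Gate libraries,
    and expresses part strengths as relative promoter/RBS units against a
    standard circuit. A synthetic fixture generator produces plate images
    and error-corrupted tagged reads with known ground truth so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    png,
    yaml,
    Biostrings,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
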