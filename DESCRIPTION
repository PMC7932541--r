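Package: srescan
Title: Detection of Composite SRE/NF-Y Elements in Gene Promoters with a
    1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Workflow for locating putative sterol-responsive-element (SRE)
    plus NF-Y composite binding regions in gene promoters. ChIP-derived SRE
    peaks with an NF-Y peak in close proximity (< 250 bp) define positive
    100-bp training windows; positives are expanded by conservation-weighted
    mutation (roulette-wheel selection over inverse phyloP-like scores) and
    strand-doubled one-hot encoding; a 1-D convolutional binary classifier
    is trained with a staged early-stopping schedule, then slid across
    500-bp promoters to call SRE/NF-Y sites by a consecutive-window rule.
    Driving bases are localised by averaged single-base occlusion, and Gene
    Ontology Biological Process terms are ranked by the odds ratio of
    positive promoters. Includes a synthetic fixture generator so the whole
    pipeline runs without any genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
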