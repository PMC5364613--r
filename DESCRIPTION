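Package: mitochron
Title: Mitogenome Chronology and Founder Analysis of Maternal Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating maternal-lineage founder events from whole
    mitochondrial genomes. Derives variant profiles from aligned mitogenomes,
    calls haplogroups against a PhyloTree-style motif database, builds
    mutation-annotated rooted trees via reduced-median network construction,
    and estimates clade coalescence ages with the rho statistic (Saillard
    standard errors) and a Poisson molecular-clock maximum-likelihood model,
    including a likelihood-ratio test for clock violation. Includes regional
    age repartitioning, founder time-window classification, cross-marker
    sex-bias summaries, and a single-locus coalescent simulator with known
    node ages for validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
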