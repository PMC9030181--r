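Package: methylrescue
Title: Quantifying Rescue of Aging-Related DNA Methylation and Expression
    Changes in Mouse Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for asking how interventions such as dietary
    restriction and chronic rapamycin attenuate aging-related DNA methylation
    and gene-expression changes. Starting from per-CpG bisulfite call tables,
    it filters sites, groups adjacent CpGs into bins, calls differentially
    methylated regions and differentially expressed genes with an
    empirical-Bayes moderated t-test, fits the genome-wide mixing coefficient
    that places a treated methylome between young and old states, applies
    direction-based amelioration rules per region and per gene, maps regions
    onto promoters and gene bodies, correlates methylation with expression
    across samples, and tests Gene Ontology over-representation with depth
    filtering. A seeded synthetic-study generator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
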