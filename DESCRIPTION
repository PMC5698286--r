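Package: kappaseq
Title: Quantification and Chromatin-Based Modelling of Immunoglobulin
    Kappa V Gene Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis of immunoglobulin kappa (Igk) V-J
    recombination from bait-capture sequencing. Processes paired-end
    VkJk-seq reads (chimaera correction, bait assignment, filtering,
    unique exact alignment, UMI-based deduplication) into a per-gene
    recombination repertoire; calls actively recombining Vk genes with a
    one-sided binomial enrichment test; builds a chromatin feature matrix
    over orientation-relative gene windows; segments the locus into
    Architectural/Enhancer/Background chromatin states with a multivariate
    negative-binomial hidden Markov model; and models recombination
    activity and frequency with a two-layer random-forest scheme including
    exhaustive subset selection over the top-ranked features. A synthetic
    data module generates a locus, annotations, chromatin tracks, peak
    calls and read pairs with planted ground truth so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
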