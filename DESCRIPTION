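Package: snvclust
Title: Clustering Subjects by Whole-Genome SNV Sets with Jaccard Distances and Neighbor-Joining Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters whole-genome sequenced subjects on the sets of single
    nucleotide variant (SNV) positions they carry. Per-subject, per-chromosome
    SNV sets are extracted from VCF files, pairwise Jaccard distances are
    computed per chromosome or genome-wide, unrooted cluster trees are built
    with a from-scratch neighbor-joining implementation, and labeled groups
    (e.g. case vs control, or two populations) are evaluated for whether they
    form clades. Also provides the descriptive layer (per-chromosome SNV
    counts, group means and standard deviations, Welch two-sample t tests,
    boxplot summaries) and a synthetic cohort generator emitting valid VCF
    plus a truth manifest, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
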