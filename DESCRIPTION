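Package: exoscreen
Title: Two-Phase Screening of Plasma Exosomal RNA Classes as Cancer Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens eight classes of plasma exosomal RNAs (miRNA, piRNA,
    lncRNA, snoRNA, snRNA, tRNA, yRNA and mRNA) as cancer diagnostic markers
    in two phases: a statistical phase that combines three normal-versus-cancer
    differential-expression contrasts on TMM-normalized counts with a
    negative-binomial exact test, and a biological phase that correlates
    per-patient chemoradiotherapy-induced expression changes (paired post/pre
    log2 fold changes) between RNA classes, counts strongly correlated partner
    RNAs per candidate, optimizes a related-partner cutoff, and builds signed
    correlation networks with Prim minimum spanning trees. Includes classical
    MDS and k-means cluster diagnosis, hierarchical clustering orders,
    patient-subgroup flagging, ROC/AUC marker-panel evaluation, and a
    negative-binomial synthetic-cohort generator with planted ground truth so
    the whole procedure is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
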