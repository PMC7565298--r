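Package: smoltmiR
Title: Integrative miRNA-mRNA Expression Analysis for Salmon Smoltification Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of an integrative
    small-RNA / microarray analysis of Atlantic salmon smoltification and
    seawater adaptation: small-RNA read quantification (adapter trimming,
    18-25 nt size selection, unique mapping to mature miRNAs), negative
    binomial differential expression of miRNA counts and Welch tests of
    log2 microarray intensities against the pre-smolt baseline, clustering
    of fold-change trajectories (Spearman distance, complete linkage, gap
    statistic), annotation of genes anti-correlated to cluster mean
    profiles, seed-constrained miRNA:3'UTR duplex minimum-free-energy
    target prediction with a nearest-neighbor energy model, Fisher's exact
    overrepresentation analysis, and aggregation of the final
    miRNA-target pair table.  A synthetic-data generator reproduces the
    statistical structure of the study design (6 timepoints x 8
    replicates, three fold-change archetypes, anti-correlated genes,
    planted high-affinity 3'UTR sites) so the whole pipeline runs and is
    validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
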