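Package: mashpan
Title: Mash-Cluster Pangenome Mining of Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups large bacterial genome collections (built for the
    Streptomyces genus) into hierarchical "Mash-clusters" and mines the
    distribution and chromosomal synteny of biosynthetic gene clusters
    (BGCs) across them. Provides MinHash genome sketching and Mash
    distances, genome quality triage (HQ/MQ/LQ), two-level K-means
    clustering refined by iterative silhouette filtering, similarity-network
    species assignment via community detection, regrouping of gene cluster
    families (GCFs) that share a MIBiG reference hit, per-cluster GCF
    distribution classes (common/accessory/unique), and a dual-edge BGC
    synteny network with conserved-backbone detection, variable-region
    extraction and dot plots. Includes a synthetic-data generator that
    plants the hierarchical population structure and BGC inventories the
    analysis assumes, so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    cluster,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    pheatmap
Config/testthat/edition: 3
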