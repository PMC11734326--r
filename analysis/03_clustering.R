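#!/usr/bin/env Rscript
# Stage 3 — two-level Mash clustering with iterative silhouette filtering.
#
# K-means on the distance-matrix rows, cluster count chosen by average
# silhouette (elbow tie-break), genomes with silhouette < 0.4 removed between
# rounds; each primary Mash-cluster is then sub-clustered the same way.

suppressPackageStartupMessages(library(mashpan))

seed <- 1L
D <- read_distance_matrix("results/mash_distances.tsv")
cfg <- clustering_config(random_seed = seed)

primary <- iterative_cluster(D, cfg)
write_cluster_rounds(primary, "results/primary_clusters.tsv")
dropped <- primary$assignment$genome_id[primary$assignment$label == "Dropped"]
cat("primary Mash-clusters:", primary$k, "over", length(primary$rounds),
    "filtering round(s);", length(dropped), "genome(s) dropped:",
    paste(dropped, collapse = " "), "\n")
print(table(primary$assignment$label))

secondary <- suppressWarnings(secondary_cluster(D, primary$assignment, cfg))
write.table(secondary$assignment, "results/secondary_clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
n_sec <- setdiff(unique(secondary$assignment$label), "Dropped")
cat("secondary Mash-clusters:", length(n_sec), "\n")
print(table(secondary$assignment$label))

plot_silhouette_curve(primary$choice, file = "results/silhouette_curve.png")
if (requireNamespace("pheatmap", quietly = TRUE)) {
  plot_distance_heatmap(D, primary$assignment,
                        file = "results/mash_heatmap.png")
}
cat("wrote results/primary_clusters.tsv, results/secondary_clusters.tsv\n")
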