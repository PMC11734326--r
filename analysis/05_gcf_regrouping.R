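#!/usr/bin/env Rscript
# Stage 5 — GCF regrouping, similarity bands and per-cluster distribution.
#
# GCFs whose members hit the same MIBiG reference at > 80% knownclusterblast
# similarity merge into one regrouped family; BGCs are tallied by similarity
# band (<50 / 50-80 / >80) and families with >= 5 BGCs are classified as
# common / accessory / unique across the primary Mash-clusters.

suppressPackageStartupMessages(library(mashpan))

bgc <- read_bgc_table("results/data/bgc_table.tsv")
prim <- read.delim("results/primary_clusters.tsv")
assignment <- data.frame(genome_id = prim$genome_id, label = prim$final)

rg <- regroup_gcfs(bgc, threshold = 80)
cat("GCF labels in:", nrow(rg$flags), "(", sum(rg$flags$known), "known )\n")
cat("regrouped families:", nrow(rg$families), "(",
    sum(rg$families$known), "known after merging )\n")
write.table(rg$families, "results/regrouped_gcfs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rg$bgc[, c("bgc_id", "gcf_id", "rgcf_id")],
            "results/bgc_families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sb <- similarity_bands(bgc)
print(sb$bands)
cat("distinct MIBiG accessions in the >80% band:",
    sb$n_top_band_accessions, "\n")
write.table(sb$bands, "results/similarity_bands.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dist <- cluster_distribution(rg, assignment, min_bgcs = 5)
print(table(dist$families$distribution_class))
write.table(dist$families, "results/distribution_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(rgcf_id = rownames(dist$abundance), dist$abundance,
                       check.names = FALSE),
            "results/cluster_abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dist$overlap, "results/cluster_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/regrouped_gcfs.tsv, distribution_classes.tsv,",
    "cluster_abundance.tsv\n")
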