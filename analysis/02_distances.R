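#!/usr/bin/env Rscript
# Stage 2 — quality triage and Mash distances.
#
# Classifies the genomes into HQ/MQ/LQ, keeps the HQ+MQ analysis set,
# sketches every genome (canonical 21-mers, bottom-1000 MinHash) and writes
# the pairwise Mash distance matrix.

suppressPackageStartupMessages(library(mashpan))

data_dir <- "results/data"
meta <- read_genome_metadata(file.path(data_dir, "genome_metadata.tsv"))
meta <- classify_quality(meta)
analysis_set <- select_analysis_set(meta)
cat("quality tiers: ", sum(meta$quality_tier == "HQ"), "HQ /",
    sum(meta$quality_tier == "MQ"), "MQ /",
    sum(meta$quality_tier == "LQ"), "LQ\n")
cat("analysis set:  ", length(analysis_set), "genomes\n")

paths <- setNames(file.path(data_dir, "fasta", paste0(analysis_set, ".fna")),
                  analysis_set)
sketches <- sketch_fasta_files(paths, k = 21, s = 1000)
D <- distance_matrix(sketches)
write_distance_matrix(D, "results/mash_distances.tsv")

ut <- upper.tri(D)
cat(sprintf("Mash distances: median %.3f, range %.4f-%.3f\n",
            median(D[ut]), min(D[ut]), max(D[ut])))
cat("wrote results/mash_distances.tsv\n")
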