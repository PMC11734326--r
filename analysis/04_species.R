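#!/usr/bin/env Rscript
# Stage 4 — species assignment for unlabeled genomes.
#
# Genomes without an input species label enter a similarity network with
# edges at > 95% whole-genome similarity (Mash distance < 0.05); Louvain
# communities become novel "MASH_sp" species, merged with the input labels.

suppressPackageStartupMessages(library(mashpan))

seed <- 1L
D <- read_distance_matrix("results/mash_distances.tsv")
meta <- read_genome_metadata("results/data/genome_metadata.tsv")
meta <- meta[meta$genome_id %in% rownames(D), ]

labeled <- meta[meta$species_label != "", c("genome_id", "species_label")]
names(labeled)[2] <- "species_id"
unlabeled <- setdiff(rownames(D), labeled$genome_id)
cat("input species labels:", length(unique(labeled$species_id)), "across",
    nrow(labeled), "genomes;", length(unlabeled), "genomes unlabeled\n")

g <- similarity_graph(D, unlabeled, threshold = 0.95)
novel <- detect_species(g, seed = seed)
merged <- merge_species(labeled, novel)
write_species(merged, "results/species.tsv")
write_similarity_graph(g, "results/species_edges.tsv",
                       "results/species_graph.graphml")

s <- merged$summary
cat("species total:", s$n_species, "(", s$n_input_species, "input +",
    s$n_novel_species, "novel );", s$n_singleton_species,
    "singleton species\n")
cat("wrote results/species.tsv, results/species_graph.graphml\n")
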