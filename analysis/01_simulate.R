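#!/usr/bin/env Rscript
# Stage 1 — simulate the study population.
#
# Plants a hierarchical genome population (3 primary clusters x 2 secondary
# subclusters x 8 strains, plus 3 unclusterable outliers) and per-genome BGC
# inventories: a 7-family conserved backbone per primary cluster, variable
# families inserted between backbone anchors per subcluster, and 4 known
# families deliberately split across GCF labels that share a MIBiG accession.

suppressPackageStartupMessages(library(mashpan))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_genomes(cfg)
write_simulated_genomes(sim, out)
meta <- simulated_metadata(sim)
write.table(meta, file.path(out, "genome_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- simulate_bgc_table(cfg, sim$truth)
write_bgc_table(tab$bgc, file.path(out, "bgc_table.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("genomes simulated:   ", length(sim$sequences), "\n")
cat("  primary clusters:  ", length(unique(stats::na.omit(sim$truth$primary))), "\n")
cat("  secondary clusters:", length(unique(stats::na.omit(sim$truth$secondary))), "\n")
cat("  outliers:          ", sum(sim$truth$is_outlier), "\n")
cat("BGC records:         ", nrow(tab$bgc), "\n")
cat("  split known families:", cfg$n_split_known_gcfs, "emitted under",
    length(unique(tab$bgc$gcf_id[grepl('^GCFK', tab$bgc$gcf_id)])),
    "GCF labels\n")
cat("outputs under", out, "\n")
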