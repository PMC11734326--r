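#' Configuration for the synthetic genome/BGC simulator
#'
#' The simulator plants a three-level population hierarchy (primary clusters
#' -> secondary subclusters -> near-identical strains, plus unclusterable
#' outliers) and, on top of it, per-genome ordered BGC inventories with a
#' conserved backbone, subcluster-specific insertions and known gene cluster
#' families deliberately split across several GCF labels. Defaults describe a
#' desk-scale population with a clean 4x separation between the
#' between-primary and within-primary divergence levels.
#'
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @param n_primary number of planted primary clusters.
#' @param n_secondary_per_primary number of secondary subclusters per primary
#'   cluster.
#' @param genomes_per_secondary genomes per secondary subcluster.
#' @param n_outliers genomes mutated far from every cluster center; they carry
#'   no planted secondary label.
#' @param genome_length genome size in bases (desk scale).
#' @param divergence_within_secondary,divergence_within_primary,divergence_between_primary
#'   expected per-base substitution fractions between genome pairs at the
#'   three hierarchy levels; must be strictly increasing.
#' @param divergence_outlier expected pairwise per-base substitution fraction
#'   between an outlier and any clustered genome; must exceed
#'   `divergence_between_primary` so outliers sit beyond every cluster.
#' @param backbone_size number of universally conserved backbone GCFs per
#'   primary cluster.
#' @param n_variable_gcfs number of variable GCFs available for insertion
#'   between backbone anchors.
#' @param p_insertion probability that a given variable GCF is present in a
#'   given secondary subcluster.
#' @param n_split_known_gcfs number of known (MIBiG-linked) GCFs that are
#'   emitted under one distinct GCF label per secondary subcluster index, so
#'   that downstream regrouping must merge them.
#' @param similarity_known,similarity_unknown length-2 ranges for
#'   knownclusterblast similarity draws of known and unknown BGCs
#'   (percentages).
#' @param p_species_labeled probability that a secondary subcluster comes with
#'   a species label in the metadata (the rest emulate genomes lacking a
#'   GTDB assignment).
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_primary = 3L,
                              n_secondary_per_primary = 2L,
                              genomes_per_secondary = 8L,
                              n_outliers = 3L,
                              genome_length = 5e4,
                              divergence_within_secondary = 0.005,
                              divergence_within_primary = 0.02,
                              divergence_between_primary = 0.1,
                              divergence_outlier = 0.15,
                              backbone_size = 7L,
                              n_variable_gcfs = 6L,
                              p_insertion = 0.5,
                              n_split_known_gcfs = 4L,
                              similarity_known = c(81, 100),
                              similarity_unknown = c(0, 50),
                              p_species_labeled = 0.5) {
  cfg <- list(seed = as.integer(seed),
              n_primary = as.integer(n_primary),
              n_secondary_per_primary = as.integer(n_secondary_per_primary),
              genomes_per_secondary = as.integer(genomes_per_secondary),
              n_outliers = as.integer(n_outliers),
              genome_length = as.numeric(genome_length),
              divergence_within_secondary = divergence_within_secondary,
              divergence_within_primary = divergence_within_primary,
              divergence_between_primary = divergence_between_primary,
              divergence_outlier = divergence_outlier,
              backbone_size = as.integer(backbone_size),
              n_variable_gcfs = as.integer(n_variable_gcfs),
              p_insertion = p_insertion,
              n_split_known_gcfs = as.integer(n_split_known_gcfs),
              similarity_known = similarity_known,
              similarity_unknown = similarity_unknown,
              p_species_labeled = p_species_labeled)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_primary", "n_secondary_per_primary", "genomes_per_secondary",
              "n_outliers", "backbone_size", "n_variable_gcfs",
              "n_split_known_gcfs")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) stop("count field '", f, "' must be >= 0")
  }
  d <- c(cfg$divergence_within_secondary, cfg$divergence_within_primary,
         cfg$divergence_between_primary)
  if (any(d < 0) || any(d > 1)) stop("divergences must be in [0, 1]")
  if (!(d[1] < d[2] && d[2] < d[3]))
    stop("divergence levels must be strictly increasing: ",
         "within_secondary < within_primary < between_primary")
  if (cfg$divergence_outlier <= cfg$divergence_between_primary)
    stop("divergence_outlier must exceed divergence_between_primary")
  for (p in c(cfg$p_insertion, cfg$p_species_labeled)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")

## substitute a Binomial(L, rate) number of positions; substitutions only, so
## pairwise sequence divergence adds (approximately) along the hierarchy
mutate_seq <- function(codes, rate) {
  n_mut <- rbinom(1L, length(codes), rate)
  if (n_mut == 0L) return(codes)
  pos <- sample.int(length(codes), n_mut)
  # draw a uniformly random *different* base at each site
  codes[pos] <- ((codes[pos] + sample(1:3, n_mut, replace = TRUE) - 1L) %% 4L) + 1L
  codes
}

#' Simulate a hierarchically structured genome population
#'
#' Generates one substitution-mutated sequence per genome down a three-level
#' hierarchy: a single root, primary-cluster centers, secondary-subcluster
#' centers, then strains. Branch substitution rates are half the target
#' pairwise divergence of each level, so expected pairwise divergences match
#' the configured `divergence_*` values. Outliers are mutated from the root at
#' `divergence_outlier` and get no secondary truth label.
#'
#' @param config a [simulation_config()].
#' @return A list with `sequences` (named character vector of genome
#'   sequences) and `truth` (data.frame: `genome_id`, `primary`, `secondary`,
#'   `is_outlier`, `species_label`).
#' @export
simulate_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_genomes <- with(config, n_primary * n_secondary_per_primary *
                      genomes_per_secondary + n_outliers)
  if (n_genomes == 0L) {
    warning("zero genomes requested")
    return(list(sequences = character(0),
                truth = data.frame(genome_id = character(0),
                                   primary = character(0),
                                   secondary = character(0),
                                   is_outlier = logical(0),
                                   species_label = character(0))))
  }
  L <- as.integer(config$genome_length)
  root <- sample.int(4L, L, replace = TRUE)

  seqs <- character(0)
  rows <- list()
  # one species label per secondary subcluster, present with p_species_labeled
  for (p in seq_len(config$n_primary)) {
    p_center <- mutate_seq(root, config$divergence_between_primary / 2)
    for (s in seq_len(config$n_secondary_per_primary)) {
      s_center <- mutate_seq(p_center, config$divergence_within_primary / 2)
      labeled <- runif(1) < config$p_species_labeled
      sp <- if (labeled) sprintf("Streptomyces sim-sp-%d-%d", p, s) else ""
      for (g in seq_len(config$genomes_per_secondary)) {
        gid <- sprintf("G_P%d_S%d_%02d", p, s, g)
        strain <- mutate_seq(s_center, config$divergence_within_secondary / 2)
        seqs[gid] <- paste(BASES[strain], collapse = "")
        rows[[gid]] <- data.frame(genome_id = gid,
                                  primary = sprintf("P%d", p),
                                  secondary = sprintf("P%d_S%d", p, s),
                                  is_outlier = FALSE,
                                  species_label = sp)
      }
    }
  }
  # root-to-outlier rate chosen so the *pairwise* outlier-to-genome
  # divergence hits the configured target (clustered genomes already sit
  # about half of each level's divergence away from the root)
  out_rate <- min(1, max(0, config$divergence_outlier -
                           config$divergence_between_primary / 2 -
                           config$divergence_within_primary / 2 -
                           config$divergence_within_secondary / 2))
  for (o in seq_len(config$n_outliers)) {
    gid <- sprintf("G_OUT_%02d", o)
    seqs[gid] <- paste(BASES[mutate_seq(root, out_rate)], collapse = "")
    rows[[gid]] <- data.frame(genome_id = gid, primary = NA_character_,
                              secondary = NA_character_, is_outlier = TRUE,
                              species_label = "")
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}

## fixed catalog of abundant BGC product types, used purely as labels
BGC_TYPES <- c("terpene", "NI-siderophore", "NRPS", "T1PKS", "RiPP-like",
               "T3PKS", "ectoine", "butyrolactone", "melanin", "T2PKS",
               "NRPS.T1PKS")

#' Simulate a BGC table over a planted genome population
#'
#' Lays out, per genome, an ordered chromosome of BGCs: the primary cluster's
#' backbone GCFs in a fixed order, with variable GCFs inserted between fixed
#' backbone anchor pairs according to secondary-subcluster membership. The
#' first `n_split_known_gcfs` backbone slots are "known" BGCs: each carries a
#' MIBiG accession shared across the whole population but a GCF label that
#' differs between secondary-subcluster indices, so the same known family
#' enters the table under several GCF labels (emulating boundary-driven
#' family splitting). All other BGCs get a low-similarity decoy hit.
#' Coordinates are 0-based half-open, non-overlapping and ascending on a
#' single chromosome contig per genome.
#'
#' @param config a [simulation_config()].
#' @param truth the truth table from [simulate_genomes()].
#' @return A list with `bgc` (data.frame in the BGC-table schema of
#'   [read_bgc_table()]) and `planted` (list describing the planted backbone,
#'   variable insertions and split known families).
#' @export
simulate_bgc_table <- function(config, truth) {
  validate_sim_config(config)
  if (config$n_variable_gcfs > 0L && config$backbone_size < 2L)
    stop("variable insertions need at least 2 backbone GCFs as anchors")
  if (config$n_split_known_gcfs > config$backbone_size)
    stop("n_split_known_gcfs cannot exceed backbone_size")
  set.seed(config$seed + 1L)

  n_known <- config$n_split_known_gcfs
  backbone <- sprintf("BB%02d", seq_len(config$backbone_size))
  accessions <- sprintf("BGC%07d", seq_len(n_known))
  # variable GCF v is anchored after backbone position anchor_after[v] and is
  # present in secondary subcluster (p, s) with probability p_insertion
  anchor_after <- if (config$n_variable_gcfs > 0L)
    sample(seq_len(config$backbone_size - 1L), config$n_variable_gcfs,
           replace = TRUE) else integer(0)
  sec_ids <- unique(truth$secondary[!truth$is_outlier])
  presence <- matrix(runif(length(sec_ids) * config$n_variable_gcfs) <
                       config$p_insertion,
                     nrow = length(sec_ids),
                     dimnames = list(sec_ids, NULL))

  bgc_len <- 20000L
  gap <- 5000L
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    gid <- truth$genome_id[i]
    if (truth$is_outlier[i]) {
      # outliers carry a short private inventory only
      gcfs <- sprintf("GCF_OUT_%s_%d", gid, 1:3)
      types <- sample(BGC_TYPES, 3L, replace = TRUE)
      known <- rep(FALSE, 3L)
      acc <- sprintf("BGC9%06d", sample.int(999999L, 3L))
    } else {
      p <- truth$primary[i]
      s_idx <- as.integer(sub(".*_S", "", truth$secondary[i]))
      gcfs <- character(0); types <- character(0)
      known <- logical(0); acc <- character(0)
      for (b in seq_len(config$backbone_size)) {
        if (b <= n_known) {
          # split known family: one label per secondary-subcluster index
          gcfs <- c(gcfs, sprintf("GCFK%02d_V%d", b, s_idx))
          known <- c(known, TRUE)
          acc <- c(acc, accessions[b])
        } else {
          gcfs <- c(gcfs, sprintf("GCF_%s_%s", p, backbone[b]))
          known <- c(known, FALSE)
          acc <- c(acc, sprintf("BGC8%06d", b))
        }
        types <- c(types, BGC_TYPES[(b - 1L) %% length(BGC_TYPES) + 1L])
        ins <- which(anchor_after == b & presence[truth$secondary[i], ])
        for (v in ins) {
          gcfs <- c(gcfs, sprintf("GCF_VAR%02d", v))
          types <- c(types, BGC_TYPES[(v - 1L) %% length(BGC_TYPES) + 1L])
          known <- c(known, FALSE)
          acc <- c(acc, sprintf("BGC7%06d", v))
        }
      }
    }
    n <- length(gcfs)
    starts <- (seq_len(n) - 1L) * (bgc_len + gap)
    sim <- ifelse(known,
                  runif(n, config$similarity_known[1], config$similarity_known[2]),
                  runif(n, config$similarity_unknown[1], config$similarity_unknown[2]))
    rows[[gid]] <- data.frame(
      bgc_id = sprintf("%s.region%03d", gid, seq_len(n)),
      genome_id = gid,
      contig_id = "chr1",
      start = starts,
      end = starts + bgc_len,
      bgc_type = types,
      on_contig_edge = FALSE,
      gcf_id = gcfs,
      mibig_hit = acc,
      kcb_similarity = round(sim, 1))
  }
  bgc <- do.call(rbind, rows)
  rownames(bgc) <- NULL
  planted <- list(backbone_size = config$backbone_size,
                  n_known = n_known,
                  accessions = accessions,
                  anchor_after = anchor_after,
                  presence = presence)
  list(bgc = bgc, planted = planted)
}

#' Expected regrouped backbone family ids for one planted primary cluster
#'
#' After GCF regrouping, the split known families collapse to one family per
#' MIBiG accession (`RGCF_<accession>`) while the unsplit backbone families
#' keep their per-primary GCF labels. The returned ids are in planted
#' chromosomal order.
#'
#' @param planted the `planted` element returned by [simulate_bgc_table()].
#' @param primary primary-cluster truth label, e.g. `"P1"`.
#' @return character vector of regrouped family ids in backbone order.
#' @export
planted_backbone <- function(planted, primary) {
  n_known <- planted$n_known
  rest <- if (planted$backbone_size > n_known)
    sprintf("GCF_%s_BB%02d", primary,
            seq(n_known + 1L, planted$backbone_size)) else character(0)
  c(sprintf("RGCF_%s", planted$accessions), rest)
}

#' Write simulated genomes to FASTA and the truth table to TSV
#'
#' @param sim output of [simulate_genomes()].
#' @param dir output directory (one FASTA per genome under `dir/fasta/`).
#' @return Invisibly, the paths written.
#' @export
write_simulated_genomes <- function(sim, dir) {
  fa_dir <- file.path(dir, "fasta")
  dir.create(fa_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (gid in names(sim$sequences)) {
    x <- Biostrings::DNAStringSet(sim$sequences[gid])
    names(x) <- gid
    p <- file.path(fa_dir, paste0(gid, ".fna"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tp))
}

#' Synthetic genome metadata in the quality-control schema
#'
#' All simulated genomes are single-contig complete assemblies; metadata
#' carries the planted species labels (empty where the subcluster was left
#' unlabeled, emulating genomes without a GTDB assignment).
#'
#' @param sim output of [simulate_genomes()].
#' @return data.frame in the schema of [read_genome_metadata()].
#' @export
simulated_metadata <- function(sim) {
  data.frame(genome_id = sim$truth$genome_id,
             assembly_level = "complete",
             n_contigs = 1L,
             n50 = nchar(sim$sequences[sim$truth$genome_id]),
             completeness = 99.5,
             contamination = 0.5,
             species_label = sim$truth$species_label,
             row.names = NULL)
}
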