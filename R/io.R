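BGC_COLUMNS <- c("bgc_id", "genome_id", "contig_id", "start", "end",
                 "bgc_type", "on_contig_edge", "gcf_id", "mibig_hit",
                 "kcb_similarity")

#' Read a BGC table TSV
#'
#' One row per detected BGC with its genome, contig, coordinates, product
#' type, contig-edge flag, input GCF label, best MIBiG hit (empty when none)
#' and knownclusterblast similarity (percent of similar genes; empty/NA when
#' there is no hit). Coordinates are normalized to 0-based half-open;
#' declare 1-based closed inputs with `coords = "1based"`.
#'
#' @param path TSV path with the required header.
#' @param coords coordinate convention of the input file.
#' @return Validated data.frame; the row count is reported via `message()`.
#' @export
read_bgc_table <- function(path, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                   colClasses = NA)
  missing <- setdiff(BGC_COLUMNS, names(df))
  if (length(missing))
    stop("BGC table lacks column(s): ", paste(missing, collapse = ", "))
  df$mibig_hit[is.na(df$mibig_hit)] <- ""
  if (coords == "1based") df$start <- df$start - 1L
  validate_bgc_table(df)
  message("read ", nrow(df), " BGC records from ", path)
  df
}

validate_bgc_table <- function(df) {
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop("start >= end at line ", bad[1] + 1L, " (bgc_id ",
         df$bgc_id[bad[1]], ")")
  if (any(df$start < 0)) stop("negative start coordinate")
  bad_sim <- which(xor(df$mibig_hit != "", !is.na(df$kcb_similarity)))
  if (length(bad_sim))
    stop("kcb_similarity must be present iff mibig_hit is present; line ",
         bad_sim[1] + 1L)
  sim <- df$kcb_similarity[!is.na(df$kcb_similarity)]
  if (length(sim) && (any(sim < 0) || any(sim > 100)))
    stop("kcb_similarity must be in [0, 100]")
  if (anyDuplicated(df$bgc_id)) stop("duplicate bgc_id values")
  # per-contig overlap / order check (warning only; order_bgcs re-sorts)
  for (key in unique(paste(df$genome_id, df$contig_id))) {
    i <- which(paste(df$genome_id, df$contig_id) == key)
    tab <- df[i, ][order(df$start[i]), ]
    if (nrow(tab) > 1L && any(tab$start[-1] < tab$end[-nrow(tab)])) {
      warning("overlapping BGCs on ", key)
      break
    }
  }
  invisible(df)
}

#' @rdname read_bgc_table
#' @param df BGC table data.frame.
#' @export
write_bgc_table <- function(df, path) {
  out <- df[, BGC_COLUMNS]
  out$mibig_hit[is.na(out$mibig_hit)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every threshold of the workflow with the conventional defaults:
#' k-mer size 21 and sketch size 1000 for Mash; silhouette cutoff 0.4 for
#' cluster refinement; 95% whole-genome similarity for species edges; 80%
#' knownclusterblast similarity for known families; similarity bands at
#' 50/80; BiG-SCAPE-style distance cutoff 0.3; at least 5 BGCs per family
#' for distribution analysis; QC thresholds 90% completeness, 5%
#' contamination, 100 contigs, 100 kb N50.
#'
#' @param seed master seed for all stochastic stages.
#' @param sim a [simulation_config()] (used when no input paths are given).
#' @param k,sketch_size Mash sketch parameters.
#' @param k_range,silhouette_cutoff,max_rounds,n_init clustering parameters
#'   (see [clustering_config()]).
#' @param species_similarity similarity threshold for species edges.
#' @param kcb_threshold knownclusterblast threshold for known families.
#' @param band_breaks similarity band break points.
#' @param bigscape_cutoff distance cutoff for list-based similarity edges.
#' @param min_bgcs minimum family size for distribution analysis.
#' @param min_completeness,max_contamination,max_contigs,min_n50 QC rules.
#' @param out_dir optional output directory; when set, every stage writes its
#'   TSV/GraphML outputs there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(seed = seed),
                            k = 21L, sketch_size = 1000L,
                            k_range = 2:20, silhouette_cutoff = 0.4,
                            max_rounds = 10L, n_init = 50L,
                            species_similarity = 0.95,
                            kcb_threshold = 80,
                            band_breaks = c(0, 50, 80, 100),
                            bigscape_cutoff = 0.3,
                            min_bgcs = 5L,
                            min_completeness = 90, max_contamination = 5,
                            max_contigs = 100, min_n50 = 1e5,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), sim = sim, k = as.integer(k),
                 sketch_size = sketch_size, k_range = k_range,
                 silhouette_cutoff = silhouette_cutoff,
                 max_rounds = max_rounds, n_init = n_init,
                 species_similarity = species_similarity,
                 kcb_threshold = kcb_threshold, band_breaks = band_breaks,
                 bigscape_cutoff = bigscape_cutoff, min_bgcs = min_bgcs,
                 min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 max_contigs = max_contigs, min_n50 = min_n50,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @param config a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, x$sim)
  x$sim <- NULL
  do.call(pipeline_config, c(x, list(sim = sim)))
}

#' Run the full Mash-cluster pangenome workflow
#'
#' Stages, in order: genome quality triage -> Mash distances -> two-level
#' iterative clustering -> similarity-network species assignment -> GCF
#' regrouping and similarity bands -> per-cluster family distribution ->
#' synteny backbone per primary cluster. Inputs are either simulated from
#' `config$sim` (default) or supplied as in-memory objects / files. The run
#' is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param metadata optional genome metadata data.frame (else simulated).
#' @param D optional precomputed distance matrix (else sketched).
#' @param bgc optional BGC table (else simulated).
#' @return list with the stage results (`metadata`, `analysis_set`, `D`,
#'   `primary`, `secondary`, `species`, `regrouped`, `bands`, `distribution`,
#'   `backbones`, `truth` when simulated) and `summary`, a flat list of counts
#'   at each stage.
#' @export
run_pipeline <- function(config = pipeline_config(), metadata = NULL,
                         D = NULL, bgc = NULL) {
  message(sprintf(
    paste0("pipeline thresholds: k=%d sketch=%s silhouette_cutoff=%.2f ",
           "species_similarity=%.2f kcb=%.0f bands=%s bigscape=%.2f ",
           "min_bgcs=%d qc=%.0f/%.0f/%d/%.0fkb seed=%d"),
    config$k, format(config$sketch_size), config$silhouette_cutoff,
    config$species_similarity, config$kcb_threshold,
    paste(config$band_breaks, collapse = "/"), config$bigscape_cutoff,
    as.integer(config$min_bgcs), config$min_completeness,
    config$max_contamination, as.integer(config$max_contigs),
    config$min_n50 / 1000, config$seed))
  truth <- NULL
  simulated <- is.null(metadata) && is.null(D) && is.null(bgc)
  if (simulated) {
    sim <- simulate_genomes(config$sim)
    truth <- sim$truth
    metadata <- simulated_metadata(sim)
    tab <- simulate_bgc_table(config$sim, sim$truth)
    bgc <- tab$bgc
  }

  ## 1. quality triage
  metadata <- classify_quality(metadata, config$min_completeness,
                               config$max_contamination, config$max_contigs,
                               config$min_n50)
  analysis_set <- select_analysis_set(metadata)
  if (length(analysis_set) < 3L) stop("stage qc: fewer than 3 genomes pass QC")

  ## 2. distances
  if (is.null(D)) {
    if (!simulated)
      stop("stage distances: supply a precomputed distance matrix (or sketch ",
           "FASTA files with sketch_fasta_files() + distance_matrix())")
    sketches <- lapply(analysis_set, function(g)
      sketch(sim$sequences[[g]], genome_id = g, k = config$k,
             s = config$sketch_size))
    D <- distance_matrix(sketches)
  } else {
    missing <- setdiff(analysis_set, rownames(D))
    if (length(missing))
      stop("stage distances: matrix lacks genome(s) ",
           paste(head(missing, 5), collapse = ", "))
    D <- D[analysis_set, analysis_set, drop = FALSE]
  }

  ## 3. two-level clustering
  ccfg <- clustering_config(k_range = config$k_range,
                            silhouette_cutoff = config$silhouette_cutoff,
                            max_rounds = config$max_rounds,
                            random_seed = config$seed,
                            n_init = config$n_init)
  primary <- iterative_cluster(D, ccfg)
  secondary <- secondary_cluster(D, primary$assignment, ccfg)

  ## 4. species network over unlabeled genomes
  labeled <- metadata[metadata$genome_id %in% analysis_set &
                        metadata$species_label != "",
                      c("genome_id", "species_label")]
  names(labeled)[2] <- "species_id"
  unlabeled <- setdiff(analysis_set, labeled$genome_id)
  sg <- similarity_graph(D, unlabeled, threshold = config$species_similarity)
  novel <- detect_species(sg, seed = config$seed)
  species <- merge_species(labeled, novel)

  ## 5. family regrouping and similarity bands
  bgc <- bgc[bgc$genome_id %in% analysis_set, , drop = FALSE]
  regrouped <- regroup_gcfs(bgc, threshold = config$kcb_threshold)
  bands <- similarity_bands(bgc, breaks = config$band_breaks)

  ## 6. family distribution across primary Mash-clusters
  distribution <- cluster_distribution(regrouped, primary$assignment,
                                       min_bgcs = config$min_bgcs)

  ## 7. synteny backbone per primary cluster
  orders <- order_bgcs(regrouped$bgc)
  backbones <- list()
  for (p in setdiff(unique(primary$assignment$label), "Dropped")) {
    ids <- primary$assignment$genome_id[primary$assignment$label == p]
    ids <- ids[ids %in% names(orders)]
    if (length(ids) >= 2L)
      backbones[[p]] <- detect_backbone(orders[ids])
  }

  summary <- list(
    n_input_genomes = nrow(metadata),
    n_hq = sum(metadata$quality_tier == "HQ"),
    n_mq = sum(metadata$quality_tier == "MQ"),
    n_lq = sum(metadata$quality_tier == "LQ"),
    n_analysis_set = length(analysis_set),
    n_primary_clusters = primary$k,
    n_primary_retained = sum(primary$assignment$label != "Dropped"),
    n_primary_dropped = sum(primary$assignment$label == "Dropped"),
    n_secondary_clusters = length(setdiff(unique(secondary$assignment$label),
                                          "Dropped")),
    n_secondary_retained = sum(secondary$assignment$label != "Dropped"),
    n_species = species$summary$n_species,
    n_singleton_species = species$summary$n_singleton_species,
    n_bgcs = nrow(bgc),
    n_gcfs = nrow(regrouped$flags),
    n_known_gcfs = sum(regrouped$flags$known),
    n_regrouped_known = sum(regrouped$families$known),
    n_families = nrow(regrouped$families),
    n_common = sum(distribution$families$distribution_class == "common"),
    n_accessory = sum(distribution$families$distribution_class == "accessory"),
    n_unique = sum(distribution$families$distribution_class == "unique"),
    backbone_sizes = vapply(backbones, function(b) length(b$backbone),
                            integer(1)))

  result <- list(metadata = metadata, analysis_set = analysis_set, D = D,
                 primary = primary, secondary = secondary, species = species,
                 regrouped = regrouped, bands = bands,
                 distribution = distribution, backbones = backbones,
                 truth = truth, summary = summary)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write.table(result$metadata, out("genome_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_distance_matrix(result$D, out("mash_distances.tsv"))
  write_cluster_rounds(result$primary, out("primary_clusters.tsv"))
  write.table(result$secondary$assignment, out("secondary_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_species(result$species, out("species.tsv"))
  write_bgc_table(result$regrouped$bgc[, BGC_COLUMNS],
                  out("bgc_table.tsv"))
  write.table(result$regrouped$families, out("regrouped_gcfs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$bands$bands, out("similarity_bands.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(rgcf_id = rownames(result$distribution$abundance),
                         result$distribution$abundance, check.names = FALSE),
              out("cluster_abundance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$distribution$families, out("distribution_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(config$out_dir)
}
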