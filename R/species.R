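#' Genome similarity graph for species delineation
#'
#' Builds an undirected graph over the genomes lacking a species label, with
#' an edge wherever whole-genome similarity `1 - D` strictly exceeds the
#' threshold (default 95%, i.e. Mash distance below 0.05 — a typical species
#' boundary).
#'
#' @param D Mash distance matrix with genome ids as dimnames.
#' @param ids genomes to include (typically the unlabeled ones); must be a
#'   subset of the matrix ids.
#' @param threshold similarity threshold in (0, 1); edge iff `1 - D > threshold`.
#' @return igraph undirected graph with vertices named by genome id.
#' @export
similarity_graph <- function(D, ids = rownames(D), threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  missing <- setdiff(ids, rownames(D))
  if (length(missing)) stop("ids not in distance matrix: ",
                            paste(missing, collapse = ", "))
  A <- (1 - D[ids, ids, drop = FALSE]) > threshold
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Assign novel species by community detection
#'
#' Louvain modularity maximization (resolution 1) partitions the similarity
#' graph; each community becomes one novel species `MASH_sp_<n>`, and
#' isolated genomes become singleton species. Connected components are
#' reported alongside so the coarser partition is available.
#'
#' @param graph similarity graph from [similarity_graph()].
#' @param seed RNG seed fixed before the (stochastic) Louvain pass.
#' @return data.frame with `genome_id`, `species_id`, `source` (always
#'   `"network"`) and `component`.
#' @export
detect_species <- function(graph, seed = 42L) {
  n <- igraph::vcount(graph)
  if (n == 0L)
    return(data.frame(genome_id = character(0), species_id = character(0),
                      source = character(0), component = integer(0)))
  set.seed(seed)
  comm <- igraph::membership(igraph::cluster_louvain(graph, resolution = 1))
  comp <- igraph::components(graph)$membership
  # renumber communities by first appearance for stable ids
  comm <- match(comm, unique(comm))
  data.frame(genome_id = igraph::V(graph)$name,
             species_id = sprintf("MASH_sp_%d", comm),
             source = "network",
             component = as.integer(comp),
             row.names = NULL)
}

#' Merge input species labels with network-derived assignments
#'
#' @param labeled data.frame with `genome_id`, `species_id` for genomes that
#'   already carry a label (e.g. from GTDB); `source` is set to `"input"`.
#' @param network_assignments result of [detect_species()] on the remaining
#'   genomes; the two genome sets must be disjoint.
#' @return list with `assignment` (one row per genome: `genome_id`,
#'   `species_id`, `source`) and `summary` (`n_species`,
#'   `n_input_species`, `n_novel_species`, `n_singleton_species`).
#' @export
merge_species <- function(labeled, network_assignments) {
  overlap <- intersect(labeled$genome_id, network_assignments$genome_id)
  if (length(overlap)) stop("genomes present in both sets: ",
                            paste(head(overlap, 5), collapse = ", "))
  lab <- data.frame(genome_id = labeled$genome_id,
                    species_id = labeled$species_id,
                    source = rep("input", nrow(labeled)))
  net <- data.frame(genome_id = network_assignments$genome_id,
                    species_id = network_assignments$species_id,
                    source = rep("network", nrow(network_assignments)))
  assignment <- rbind(lab, net)
  counts <- table(assignment$species_id)
  list(assignment = assignment,
       summary = list(n_species = length(unique(assignment$species_id)),
                      n_input_species = length(unique(lab$species_id)),
                      n_novel_species = length(unique(net$species_id)),
                      n_singleton_species = sum(counts == 1L)))
}

#' Write a species assignment TSV and graph exports
#'
#' @param merged result of [merge_species()].
#' @param path output TSV path (`genome_id`, `species_id`, `source`).
#' @export
write_species <- function(merged, path) {
  write.table(merged$assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_species
#' @param graph igraph object.
#' @param edges_path path for the edge-list TSV.
#' @param graphml_path optional path for a GraphML export.
#' @export
write_similarity_graph <- function(graph, edges_path, graphml_path = NULL) {
  el <- igraph::as_edgelist(graph)
  write.table(data.frame(genome_a = el[, 1], genome_b = el[, 2]),
              edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  invisible(edges_path)
}
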