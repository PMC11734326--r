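#' Configuration for two-level Mash clustering
#'
#' @param k_range candidate cluster counts for K-means (default 2..20;
#'   truncated to the data size with a warning when needed).
#' @param silhouette_cutoff per-genome silhouette threshold below which a
#'   genome is removed between rounds (default 0.4).
#' @param max_rounds cap on filtering iterations (default 10).
#' @param random_seed seed set before every K-means sweep.
#' @param n_init number of K-means restarts (`nstart`).
#' @param silhouette_metric `"mash"` scores silhouettes on the precomputed
#'   Mash distance matrix (default, so scores reflect the genomic distance
#'   being interpreted); `"euclidean"` scores them on the K-means feature
#'   space.
#' @return list of class `clustering_config`.
#' @export
clustering_config <- function(k_range = 2:20,
                              silhouette_cutoff = 0.4,
                              max_rounds = 10L,
                              random_seed = 42L,
                              n_init = 50L,
                              silhouette_metric = c("mash", "euclidean")) {
  if (length(k_range) == 0L) stop("k_range must be non-empty")
  if (silhouette_cutoff <= -1 || silhouette_cutoff >= 1)
    stop("silhouette_cutoff must be in (-1, 1)")
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 silhouette_cutoff = silhouette_cutoff,
                 max_rounds = as.integer(max_rounds),
                 random_seed = as.integer(random_seed),
                 n_init = as.integer(n_init),
                 silhouette_metric = match.arg(silhouette_metric)),
            class = "clustering_config")
}

#' Feature rows and correlation distance from a distance matrix
#'
#' Each genome is represented by its row of the Mash distance matrix; these
#' rows are the K-means feature vectors. For dendrogram/heatmap ordering the
#' genome-by-genome Pearson correlation distance (1 - r between rows) is also
#' returned; pairs involving a constant (zero-variance) row get correlation
#' distance 1 with a warning.
#'
#' @param D symmetric distance matrix with genome ids as dimnames.
#' @return list with `features` (matrix, one row per genome) and `cor_dist`
#'   (genome-by-genome correlation-distance matrix, zero diagonal).
#' @export
feature_rows <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  sds <- apply(D, 1L, stats::sd)
  cd <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
  ok <- sds > 0
  if (any(!ok)) warning("constant distance row(s): correlation distance set to 1")
  if (sum(ok) >= 2L) {
    r <- suppressWarnings(stats::cor(t(D[ok, ok, drop = FALSE])))
    cd[ok, ok] <- 1 - r
  }
  diag(cd) <- 0
  list(features = D, cor_dist = cd)
}

## silhouette widths of an integer labeling, on the chosen metric
sil_widths <- function(labels, D, features, metric) {
  dm <- if (metric == "mash") D else as.matrix(stats::dist(features))
  sw <- cluster::silhouette(labels, dmatrix = dm)
  setNames(sw[, "sil_width"], rownames(D))
}

## relabel cluster ids to 1..k by order of first appearance (deterministic)
relabel <- function(labels) {
  match(labels, unique(labels))
}

#' Choose the number of K-means clusters by silhouette and elbow
#'
#' Runs K-means on the distance-matrix rows for each candidate `k` (fixed
#' seed, `n_init` restarts), scores each solution by the average silhouette on
#' the configured metric, and picks the `k` maximizing it. Silhouette ties
#' (within 1e-8, e.g. on data with no structure) are broken by the elbow of
#' the inertia curve — the largest second difference of inertia normalized by
#' the one-cluster inertia — and finally by the smaller `k`.
#'
#' @param features feature matrix (rows of the distance matrix).
#' @param D distance matrix used for silhouette scoring.
#' @param config a [clustering_config()].
#' @return list with `k` (chosen), `k_range`, `silhouette` (average per k),
#'   `inertia` (per k, normalized), `labels` (matrix of relabeled assignments,
#'   one column per k).
#' @export
choose_k <- function(features, D, config = clustering_config()) {
  n <- nrow(features)
  k_range <- config$k_range
  if (max(k_range) > n - 1L) {
    k_range <- k_range[k_range <= n - 1L]
    warning("k_range truncated to 2..", n - 1L, " for ", n, " genomes")
  }
  if (length(k_range) == 0L) stop("no feasible k for ", n, " genomes")
  tss <- sum(scale(features, scale = FALSE)^2)   # k = 1 inertia
  sil <- inertia <- setNames(numeric(length(k_range)), k_range)
  labs <- matrix(NA_integer_, n, length(k_range),
                 dimnames = list(rownames(features), k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(config$random_seed)
    km <- suppressWarnings(kmeans(features, centers = k, nstart = config$n_init,
                                  iter.max = 100L))
    lab <- relabel(km$cluster)
    labs[, i] <- lab
    inertia[i] <- km$tot.withinss / tss
    sil[i] <- mean(sil_widths(lab, D, features, config$silhouette_metric))
  }
  tied <- which(sil >= max(sil) - 1e-8)
  if (length(tied) > 1L) {
    # elbow: largest second difference of the normalized inertia curve
    d2 <- rep(-Inf, length(k_range))
    if (length(k_range) >= 3L)
      d2[2:(length(k_range) - 1L)] <- diff(inertia, differences = 2L)
    best <- tied[order(-d2[tied], k_range[tied])][1L]
  } else best <- tied
  list(k = k_range[best], k_range = k_range, silhouette = sil,
       inertia = inertia, labels = labs)
}

#' Iterative silhouette-filtered clustering
#'
#' Round r: choose the cluster count on the retained genomes, assign by
#' K-means, then drop every genome whose silhouette is below the cutoff.
#' Repeats until no genome is dropped or `max_rounds` is hit; every retained
#' genome's final silhouette is at or above the cutoff.
#'
#' @param D symmetric distance matrix with genome ids as dimnames.
#' @param config a [clustering_config()].
#' @param label_prefix prefix for final cluster labels (default `"M"`, giving
#'   M1, M2, ...).
#' @return list of class `mash_clustering` with `rounds` (one data.frame per
#'   round: `genome_id`, `cluster`, `silhouette`; dropped genomes carry
#'   `"Dropped"`), `assignment` (final data.frame: `genome_id`, `label`,
#'   `silhouette`), `k`, `dropped_round` (named integer: round at which each
#'   dropped genome was removed) and `choice` (the final [choose_k()] result).
#' @export
iterative_cluster <- function(D, config = clustering_config(),
                              label_prefix = "M") {
  ids <- rownames(D)
  if (length(ids) < 3L) stop("need at least 3 genomes to cluster")
  retained <- ids
  dropped_round <- integer(0)
  rounds <- list()
  choice <- NULL
  for (r in seq_len(config$max_rounds)) {
    if (length(retained) < 3L)
      stop("no stable clustering at this cutoff: ",
           length(retained), " genome(s) left in round ", r)
    Dr <- D[retained, retained, drop = FALSE]
    fr <- feature_rows(Dr)
    choice <- choose_k(fr$features, Dr, config)
    lab <- choice$labels[, as.character(choice$k)]
    sw <- sil_widths(lab, Dr, fr$features, config$silhouette_metric)
    round_df <- data.frame(genome_id = ids,
                           cluster = "Dropped",
                           silhouette = NA_real_)
    m <- match(retained, ids)
    round_df$cluster[m] <- as.character(lab)
    round_df$silhouette[m] <- sw
    rounds[[r]] <- round_df
    low <- retained[sw < config$silhouette_cutoff]
    if (length(low) == 0L) break
    dropped_round[low] <- r
    retained <- setdiff(retained, low)
    if (length(retained) == 0L)
      stop("no stable clustering at this cutoff: all genomes dropped")
  }
  final <- rounds[[length(rounds)]]
  # genomes still pending removal when max_rounds is hit are dropped too, so
  # every retained genome's final silhouette is >= the cutoff
  lab <- ifelse(final$cluster == "Dropped" | !(ids %in% retained), "Dropped",
                paste0(label_prefix, final$cluster))
  assignment <- data.frame(genome_id = ids, label = lab,
                           silhouette = final$silhouette)
  structure(list(rounds = rounds, assignment = assignment,
                 k = choice$k, dropped_round = dropped_round,
                 choice = choice),
            class = "mash_clustering")
}

#' Secondary clustering within each primary Mash-cluster
#'
#' Applies [iterative_cluster()] independently to the distance sub-matrix of
#' each primary cluster. Secondary labels are formatted `"M<i>_<j>"`. Primary
#' clusters with fewer than 3 genomes, or in which no stable sub-structure
#' survives the silhouette cutoff, are passed through unsplit as `"M<i>_1"`
#' with a warning.
#'
#' @param D full distance matrix.
#' @param primary_assignment the `assignment` data.frame of the primary
#'   [iterative_cluster()] run (labels `"M<i>"` or `"Dropped"`).
#' @param config a [clustering_config()].
#' @return list with `assignment` (data.frame: `genome_id`, `label`
#'   (`"M<i>_<j>"` or `"Dropped"`), `silhouette`), `per_primary` (list of
#'   `mash_clustering` objects or `NULL` where unsplit) and `unsplit`
#'   (character vector of unsplit primary labels).
#' @export
secondary_cluster <- function(D, primary_assignment,
                              config = clustering_config()) {
  prim <- setdiff(unique(primary_assignment$label), "Dropped")
  prim <- prim[order(as.integer(sub("^\\D+", "", prim)))]
  out <- data.frame(genome_id = primary_assignment$genome_id,
                    label = "Dropped", silhouette = NA_real_)
  per_primary <- list()
  unsplit <- character(0)
  for (p in prim) {
    ids <- primary_assignment$genome_id[primary_assignment$label == p]
    if (length(ids) < 3L) {
      warning(p, " has fewer than 3 genomes; kept unsplit as ", p, "_1")
      out$label[out$genome_id %in% ids] <- paste0(p, "_1")
      unsplit <- c(unsplit, p)
      per_primary[[p]] <- NULL
      next
    }
    res <- tryCatch(
      iterative_cluster(D[ids, ids, drop = FALSE], config,
                        label_prefix = paste0(p, "_")),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(p, ": no stable sub-structure (", conditionMessage(res),
              "); kept unsplit as ", p, "_1")
      out$label[out$genome_id %in% ids] <- paste0(p, "_1")
      unsplit <- c(unsplit, p)
      next
    }
    per_primary[[p]] <- res
    m <- match(res$assignment$genome_id, out$genome_id)
    out$label[m] <- res$assignment$label
    out$silhouette[m] <- res$assignment$silhouette
  }
  list(assignment = out, per_primary = per_primary, unsplit = unsplit)
}

#' Write per-round cluster assignments as TSV
#'
#' One row per genome; for each filtering round a cluster column (label or
#' `"Dropped"`) and a silhouette column, plus the final label.
#'
#' @param clustering a `mash_clustering` object.
#' @param path output TSV path.
#' @export
write_cluster_rounds <- function(clustering, path) {
  df <- data.frame(genome_id = clustering$assignment$genome_id)
  for (r in seq_along(clustering$rounds)) {
    df[[paste0("cluster_round_", r)]] <- clustering$rounds[[r]]$cluster
    df[[paste0("silhouette_round_", r)]] <- clustering$rounds[[r]]$silhouette
  }
  df$final <- clustering$assignment$label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the average-silhouette and inertia curves of a choose_k sweep
#'
#' @param choice result of [choose_k()] (also stored in
#'   `mash_clustering$choice`).
#' @param file optional PNG path; plots to the active device when `NULL`.
#' @export
plot_silhouette_curve <- function(choice, file = NULL) {
  if (!is.null(file)) { grDevices::png(file, 800, 500); on.exit(grDevices::dev.off()) }
  op <- graphics::par(mar = c(4, 4, 2, 4)); on.exit(graphics::par(op), add = TRUE)
  plot(choice$k_range, choice$silhouette, type = "b", pch = 19,
       xlab = "number of clusters k", ylab = "average silhouette",
       main = "cluster-count selection")
  graphics::abline(v = choice$k, lty = 2)
  graphics::par(new = TRUE)
  plot(choice$k_range, choice$inertia, type = "l", col = "grey50",
       axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("normalized inertia", side = 4, line = 2.5, col = "grey40")
  invisible(choice$k)
}

#' Distance-matrix heatmap ordered by hierarchical clustering
#'
#' Rows/columns are ordered by Ward (ward.D2) hierarchical clustering of the
#' Pearson correlation distance between distance-matrix rows; column
#' annotation shows the Mash-cluster labels.
#'
#' @param D distance matrix.
#' @param assignment final assignment data.frame (`genome_id`, `label`).
#' @param file optional PNG path.
#' @export
plot_distance_heatmap <- function(D, assignment = NULL, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_distance_heatmap needs the 'pheatmap' package")
  hc <- stats::hclust(stats::as.dist(feature_rows(D)$cor_dist), method = "ward.D2")
  ann <- NULL
  if (!is.null(assignment)) {
    ann <- data.frame(cluster = assignment$label,
                      row.names = assignment$genome_id)
  }
  pheatmap::pheatmap(D, cluster_rows = hc, cluster_cols = hc,
                     annotation_col = ann, show_rownames = FALSE,
                     show_colnames = FALSE,
                     filename = if (is.null(file)) NA else file)
}
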