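#' Per-genome chromosomal order of BGCs
#'
#' Sorts each genome's BGCs by (contig, start), breaking start ties by end
#' then BGC id, and assigns ordinal positions within each contig. Overlapping
#' BGCs on a contig are kept in start order with a warning. Ordering evidence
#' never crosses contig boundaries, so backbone analysis is most informative
#' on complete (single-contig) assemblies.
#'
#' @param bgc BGC table, optionally carrying an `rgcf_id` column from
#'   [regroup_gcfs()].
#' @param genomes genomes to order (default: all in the table).
#' @return Named list (by genome) of data.frames sorted in chromosomal order
#'   with a `position` column (ordinal within contig).
#' @export
order_bgcs <- function(bgc, genomes = unique(bgc$genome_id)) {
  out <- list()
  warned <- FALSE
  for (g in genomes) {
    tab <- bgc[bgc$genome_id == g, , drop = FALSE]
    ord <- order(tab$contig_id, tab$start, tab$end, tab$bgc_id)
    tab <- tab[ord, , drop = FALSE]
    pos <- stats::ave(tab$start, tab$contig_id, FUN = seq_along)
    tab$position <- as.integer(pos)
    if (!warned) {
      ov <- unlist(tapply(seq_len(nrow(tab)), tab$contig_id, function(i) {
        if (length(i) < 2L) return(FALSE)
        any(tab$start[i][-1] < tab$end[i][-length(i)])
      }))
      if (any(ov)) {
        warning("overlapping BGCs in genome ", g, "; kept in start order")
        warned <- TRUE
      }
    }
    rownames(tab) <- NULL
    out[[g]] <- tab
  }
  out
}

#' Build the dual-edge BGC synteny network
#'
#' Nodes are BGCs (attributes: genome, contig, position, family, type).
#' Adjacency edges connect consecutive BGCs on each contig (one simple path
#' per contig). Similarity edges come either from regrouped-family
#' co-membership (clique per family) or from a pairwise BGC distance list
#' with a cutoff (default 0.3, the conventional BiG-SCAPE threshold); their
#' weight is 1 or `1 - distance` respectively.
#'
#' @param orders per-genome ordered BGC lists from [order_bgcs()].
#' @param similarity `"comembership"` (default; uses the `rgcf_id` column) or
#'   a data.frame `bgc_a`, `bgc_b`, `distance`.
#' @param cutoff distance cutoff for list-based similarity edges.
#' @return list of class `synteny_graph`: `graph` (igraph with edge attribute
#'   `type` in adjacency/similarity) and `orders`.
#' @export
build_synteny_graph <- function(orders, similarity = "comembership",
                                cutoff = 0.3) {
  tab <- do.call(rbind, orders)
  rownames(tab) <- NULL
  fam <- if (!is.null(tab$rgcf_id)) tab$rgcf_id else tab$gcf_id
  g <- igraph::make_empty_graph(n = nrow(tab), directed = FALSE)
  igraph::V(g)$name <- tab$bgc_id
  igraph::V(g)$genome <- tab$genome_id
  igraph::V(g)$contig <- tab$contig_id
  igraph::V(g)$position <- tab$position
  igraph::V(g)$family <- fam
  igraph::V(g)$bgc_type <- tab$bgc_type

  adj <- do.call(rbind, lapply(orders, function(o) {
    do.call(rbind, lapply(split(o$bgc_id, o$contig_id), function(ids) {
      if (length(ids) < 2L) return(NULL)
      cbind(ids[-length(ids)], ids[-1])
    }))
  }))
  if (!is.null(adj) && nrow(adj)) {
    g <- igraph::add_edges(g, t(adj), type = "adjacency", weight = 1)
  }

  if (identical(similarity, "comembership")) {
    sim <- do.call(rbind, lapply(split(tab$bgc_id, fam), function(ids) {
      if (length(ids) < 2L) return(NULL)
      t(utils::combn(sort(ids), 2L))
    }))
    w <- if (is.null(sim)) numeric(0) else rep(1, nrow(sim))
  } else {
    stopifnot(is.data.frame(similarity))
    unknown <- setdiff(c(similarity$bgc_a, similarity$bgc_b), tab$bgc_id)
    if (length(unknown)) stop("distance list references unknown BGCs: ",
                              paste(head(unknown, 5), collapse = ", "))
    keep <- similarity$distance <= cutoff & similarity$bgc_a != similarity$bgc_b
    sim <- as.matrix(similarity[keep, c("bgc_a", "bgc_b")])
    w <- 1 - similarity$distance[keep]
  }
  if (!is.null(sim) && nrow(sim)) {
    g <- igraph::add_edges(g, t(sim), type = "similarity", weight = w)
  }
  structure(list(graph = g, orders = orders), class = "synteny_graph")
}

## per-genome projected family order: families restricted to `candidates`,
## multi-copy families collapsed to their first chromosomal occurrence
project_order <- function(order_df, candidates) {
  fam <- if (!is.null(order_df$rgcf_id)) order_df$rgcf_id else order_df$gcf_id
  fam <- fam[fam %in% candidates]
  unique(fam)
}

## count, per unordered family pair, in how many genomes the pair's relative
## order disagrees with the consensus after the genome's best orientation
pair_conflicts <- function(projections, consensus) {
  conflicts <- list()
  for (p in projections) {
    pf <- p[p %in% consensus]
    fwd <- match(pf, consensus)
    n_disc_f <- sum(outer(fwd, fwd, ">")[upper.tri(diag(length(fwd)))])
    use <- if (n_disc_f <= choose(length(fwd), 2) / 2) pf else rev(pf)
    idx <- match(use, consensus)
    if (length(idx) < 2L) next
    for (i in seq_len(length(idx) - 1L)) {
      for (j in seq((i + 1L), length(idx))) {
        if (idx[i] > idx[j]) {
          key <- paste(sort(c(use[i], use[j])), collapse = "\r")
          conflicts[[key]] <- (conflicts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  conflicts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the conserved BGC backbone of a genome group
#'
#' Candidate families are those present in at least `min_presence` of the
#' group's genomes. Each genome's chromosome order is projected onto the
#' candidates (multi-copy families collapse to their first occurrence,
#' flagged); the consensus is the projection of the reference genome (the one
#' with the most BGCs; ties broken by genome id). The backbone is consistent
#' when every projection equals the consensus or its exact reversal —
#' assembly orientation is arbitrary, so reversal is never a conflict. If
#' inconsistent, families are removed greedily — always the family involved
#' in the most pairwise order conflicts (ties: lexicographically smallest) —
#' until the rest is consistent.
#'
#' @param x a `synteny_graph` from [build_synteny_graph()] or a list of
#'   per-genome orders from [order_bgcs()].
#' @param genomes genomes of the group (default: all).
#' @param min_presence minimum fraction of genomes a candidate family must
#'   occur in (default 1 = all).
#' @return list of class `backbone_result`: `backbone` (ordered family ids),
#'   `orders` (per-genome projected orders), `orientation` (named
#'   forward/reversed), `consistent` (TRUE once conflicts are resolved),
#'   `removed` (families excluded by conflict resolution), `multi_copy`
#'   (families seen more than once in some genome).
#' @export
detect_backbone <- function(x, genomes = NULL, min_presence = 1.0) {
  orders <- if (inherits(x, "synteny_graph")) x$orders else x
  if (is.null(genomes)) genomes <- names(orders)
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  orders <- orders[genomes]

  fam_of <- function(o) if (!is.null(o$rgcf_id)) o$rgcf_id else o$gcf_id
  presence <- table(unlist(lapply(orders, function(o) unique(fam_of(o)))))
  candidates <- names(presence)[presence >= min_presence * length(genomes)]
  if (length(candidates) == 0L) {
    warning("no candidate backbone families at min_presence = ", min_presence)
    return(structure(list(backbone = character(0), orders = NULL,
                          orientation = NULL, consistent = FALSE,
                          removed = character(0), multi_copy = character(0)),
                     class = "backbone_result"))
  }
  multi_copy <- unique(unlist(lapply(orders, function(o) {
    f <- fam_of(o)[fam_of(o) %in% candidates]
    unique(f[duplicated(f)])
  })))

  n_bgcs <- vapply(orders, nrow, integer(1))
  ref <- genomes[order(-n_bgcs, genomes)][1L]
  kept <- candidates
  repeat {
    consensus <- project_order(orders[[ref]], kept)
    projections <- lapply(orders, project_order, candidates = kept)
    orientation <- vapply(projections, function(p) {
      pf <- p[p %in% consensus]
      cns <- consensus[consensus %in% pf]
      if (identical(pf, cns)) "forward"
      else if (identical(pf, rev(cns))) "reversed"
      else NA_character_
    }, character(1))
    if (!anyNA(orientation)) break
    conf <- pair_conflicts(projections, consensus)
    if (length(conf) == 0L) break   # inconsistency not expressible pairwise
    score <- setNames(numeric(length(kept)), kept)
    for (key in names(conf)) {
      pr <- strsplit(key, "\r", fixed = TRUE)[[1]]
      score[pr] <- score[pr] + conf[[key]]
    }
    worst <- names(score)[order(-score, names(score))][1L]
    kept <- setdiff(kept, worst)
    if (length(kept) == 0L) break
  }
  consensus <- project_order(orders[[ref]], kept)
  projections <- lapply(orders, project_order, candidates = kept)
  orient <- function(consensus) vapply(projections, function(p) {
    pf <- p[p %in% consensus]
    cns <- consensus[consensus %in% pf]
    if (identical(pf, cns)) "forward"
    else if (identical(pf, rev(cns))) "reversed"
    else NA_character_
  }, character(1))
  orientation <- orient(consensus)
  # canonicalize: the consensus direction is the majority orientation, so the
  # result is invariant to which genome happens to be stored flipped
  if (sum(orientation == "reversed", na.rm = TRUE) >
      sum(orientation == "forward", na.rm = TRUE)) {
    consensus <- rev(consensus)
    orientation <- orient(consensus)
  }
  structure(list(backbone = consensus,
                 orders = projections,
                 orientation = orientation,
                 consistent = !anyNA(orientation),
                 removed = setdiff(candidates, kept),
                 multi_copy = multi_copy),
            class = "backbone_result")
}

#' Variable region between two backbone anchors
#'
#' For each genome, returns the (possibly empty) ordered BGCs strictly
#' between the first occurrences of the two anchor families, reported in the
#' consensus orientation (reversed genomes are flipped so region contents are
#' comparable across genomes). Anchors that are not adjacent in the backbone
#' span the intermediate backbone families, with a warning.
#'
#' @param x a `synteny_graph` or per-genome orders list.
#' @param backbone a `backbone_result` from [detect_backbone()].
#' @param anchors length-2 character vector of backbone family ids.
#' @return Named list (by genome) of data.frames of the BGCs in the region.
#' @export
variable_regions <- function(x, backbone, anchors) {
  orders <- if (inherits(x, "synteny_graph")) x$orders else x
  if (!all(anchors %in% backbone$backbone))
    stop("both anchors must be backbone families")
  ia <- match(anchors, backbone$backbone)
  if (abs(diff(ia)) > 1L)
    warning("anchors are not adjacent in the backbone; region spans ",
            abs(diff(ia)) - 1L, " intermediate backbone families")
  genomes <- names(backbone$orientation)
  out <- list()
  for (g in genomes) {
    o <- orders[[g]]
    fam <- if (!is.null(o$rgcf_id)) o$rgcf_id else o$gcf_id
    pos <- match(anchors, fam)   # first occurrences
    if (anyNA(pos)) { out[[g]] <- o[0, , drop = FALSE]; next }
    lo <- min(pos); hi <- max(pos)
    region <- if (hi - lo > 1L) o[(lo + 1L):(hi - 1L), , drop = FALSE]
      else o[0, , drop = FALSE]
    if (identical(backbone$orientation[[g]], "reversed") && nrow(region) > 1L)
      region <- region[rev(seq_len(nrow(region))), , drop = FALSE]
    rownames(region) <- NULL
    out[[g]] <- region
  }
  out
}

#' Synteny dot plot point set for two genomes
#'
#' One point per pair of BGCs (one from each genome) belonging to the same
#' family; a collinear diagonal indicates conserved synteny.
#'
#' @param order_a,order_b ordered BGC data.frames from [order_bgcs()].
#' @return data.frame with columns `i`, `j` (ordinal positions in genome A
#'   and B) and `family`.
#' @export
dotplot_points <- function(order_a, order_b) {
  fam_a <- if (!is.null(order_a$rgcf_id)) order_a$rgcf_id else order_a$gcf_id
  fam_b <- if (!is.null(order_b$rgcf_id)) order_b$rgcf_id else order_b$gcf_id
  hit <- which(outer(fam_a, fam_b, "=="), arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2], family = fam_a[hit[, 1]],
             row.names = NULL)
}

#' @rdname dotplot_points
#' @param file optional PNG path.
#' @param labels axis labels (genome ids).
#' @export
plot_dotplot <- function(order_a, order_b, labels = c("genome A", "genome B"),
                         file = NULL) {
  pts <- dotplot_points(order_a, order_b)
  if (!is.null(file)) { grDevices::png(file, 600, 600); on.exit(grDevices::dev.off()) }
  plot(pts$i, pts$j, pch = 19, xlab = paste(labels[1], "BGC position"),
       ylab = paste(labels[2], "BGC position"), main = "BGC synteny dot plot")
  invisible(pts)
}

#' Export a synteny graph for Cytoscape and GraphML consumers
#'
#' @param sg a `synteny_graph`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @export
write_synteny_graph <- function(sg, prefix) {
  g <- sg$graph
  nodes <- data.frame(bgc_id = igraph::V(g)$name,
                      genome = igraph::V(g)$genome,
                      contig = igraph::V(g)$contig,
                      position = igraph::V(g)$position,
                      family = igraph::V(g)$family,
                      bgc_type = igraph::V(g)$bgc_type)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(bgc_a = el[, 1], bgc_b = el[, 2],
                      type = igraph::E(g)$type,
                      weight = igraph::E(g)$weight)
  write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
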