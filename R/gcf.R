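#' Flag known GCFs from knownclusterblast similarity
#'
#' A gene cluster family (GCF) is called "known" when at least one member BGC
#' hits a MIBiG reference with knownclusterblast similarity strictly above the
#' threshold (default 80% of genes). The family is assigned the MIBiG
#' accession with the most above-threshold member hits; ties are broken by
#' the highest mean similarity among those hits, then by the
#' lexicographically smallest accession.
#'
#' @param bgc BGC table (see [read_bgc_table()]); every BGC must carry a
#'   `gcf_id`.
#' @param threshold similarity threshold, strict (default 80).
#' @return data.frame with one row per GCF: `gcf_id`, `known`,
#'   `mibig_accession` (empty when unknown), `n_bgcs`.
#' @export
flag_known_gcfs <- function(bgc, threshold = 80) {
  if (anyNA(bgc$gcf_id) || any(bgc$gcf_id == ""))
    stop("every BGC must have a gcf_id")
  gcfs <- unique(bgc$gcf_id)
  hit <- !is.na(bgc$kcb_similarity) & bgc$mibig_hit != "" &
    bgc$kcb_similarity > threshold
  out <- data.frame(gcf_id = gcfs, known = FALSE, mibig_accession = "",
                    n_bgcs = as.integer(table(bgc$gcf_id)[gcfs]))
  hits <- bgc[hit, c("gcf_id", "mibig_hit", "kcb_similarity")]
  if (nrow(hits)) {
    for (g in unique(hits$gcf_id)) {
      h <- hits[hits$gcf_id == g, ]
      agg <- aggregate(kcb_similarity ~ mibig_hit, h,
                       function(x) c(n = length(x), mean = mean(x)))
      n <- agg$kcb_similarity[, "n"]
      m <- agg$kcb_similarity[, "mean"]
      best <- order(-n, -m, agg$mibig_hit)[1L]
      i <- out$gcf_id == g
      out$known[i] <- TRUE
      out$mibig_accession[i] <- agg$mibig_hit[best]
    }
  }
  out
}

#' Regroup GCFs that share a MIBiG hit
#'
#' Known GCFs assigned to the same MIBiG accession merge into a single
#' "regrouped" GCF named `RGCF_<accession>`; unknown GCFs pass through
#' one-to-one under their input label. The operation is idempotent and never
#' increases the family count.
#'
#' MIBiG entries encoding the same compound (e.g. the two ectoine entries)
#' are *not* merged by default — compound identity is external knowledge. A
#' `compound_map` (columns `accession`, `compound`) switches the merge key to
#' the compound for the accessions it lists.
#'
#' @param bgc BGC table.
#' @param threshold knownclusterblast threshold passed to
#'   [flag_known_gcfs()].
#' @param compound_map optional data.frame (`accession`, `compound`) enabling
#'   compound-level merging of known families.
#' @return list of class `regrouped_gcfs` with `bgc` (input table plus an
#'   `rgcf_id` column), `families` (one row per regrouped family: `rgcf_id`,
#'   `known`, `mibig_accession`, `n_member_gcfs`, `member_gcf_ids`
#'   (comma-separated), `n_bgcs`) and `flags` (the [flag_known_gcfs()]
#'   table).
#' @export
regroup_gcfs <- function(bgc, threshold = 80, compound_map = NULL) {
  flags <- flag_known_gcfs(bgc, threshold)
  key <- flags$mibig_accession
  if (!is.null(compound_map)) {
    m <- match(key, compound_map$accession)
    key[!is.na(m)] <- compound_map$compound[m[!is.na(m)]]
  }
  rg <- ifelse(flags$known, paste0("RGCF_", key), flags$gcf_id)
  # already-regrouped known families keep their id (idempotence)
  already <- flags$known & startsWith(flags$gcf_id, "RGCF_")
  rg[already] <- flags$gcf_id[already]
  map <- setNames(rg, flags$gcf_id)
  bgc$rgcf_id <- unname(map[bgc$gcf_id])
  fam <- aggregate(list(n_member_gcfs = flags$gcf_id),
                   by = list(rgcf_id = rg),
                   FUN = function(x) length(unique(x)))
  fam$member_gcf_ids <- vapply(fam$rgcf_id, function(r)
    paste(sort(unique(flags$gcf_id[map[flags$gcf_id] == r])), collapse = ","),
    character(1))
  fam$known <- vapply(fam$rgcf_id, function(r)
    any(flags$known[map[flags$gcf_id] == r]), logical(1))
  fam$mibig_accession <- vapply(fam$rgcf_id, function(r) {
    acc <- unique(flags$mibig_accession[map[flags$gcf_id] == r & flags$known])
    if (length(acc)) acc[1] else ""
  }, character(1))
  fam$n_bgcs <- as.integer(table(bgc$rgcf_id)[fam$rgcf_id])
  structure(list(bgc = bgc,
                 families = fam[, c("rgcf_id", "known", "mibig_accession",
                                    "n_member_gcfs", "member_gcf_ids", "n_bgcs")],
                 flags = flags),
            class = "regrouped_gcfs")
}

#' Tally BGCs by knownclusterblast similarity band
#'
#' Counts BGCs per similarity band, overall and per BGC type, and the number
#' of distinct MIBiG accessions matched in the top band. Default bands follow
#' the conventional coloring: below 50%, 50-80%, above 80%. BGCs without a
#' MIBiG hit (or with missing similarity) fall in the lowest band.
#'
#' @param bgc BGC table.
#' @param breaks increasing numeric break points spanning `[0, 100]`
#'   (default `c(0, 50, 80, 100)`); bands are `(b_i, b_{i+1}]` with the first
#'   band closed at 0.
#' @return list with `bands` (data.frame: `band`, `n_bgcs`), `by_type`
#'   (band-by-type count matrix) and `n_top_band_accessions`.
#' @export
similarity_bands <- function(bgc, breaks = c(0, 50, 80, 100)) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("bands overlap: breaks must be strictly increasing")
  if (breaks[1] > 0 || breaks[length(breaks)] < 100)
    stop("breaks must span [0, 100]")
  sim <- bgc$kcb_similarity
  sim[is.na(sim) | bgc$mibig_hit == ""] <- 0
  band <- cut(sim, breaks, include.lowest = TRUE, right = TRUE)
  levels(band) <- paste0(breaks[-length(breaks)], "-", breaks[-1], "%")
  top <- band == levels(band)[nlevels(band)]
  list(bands = data.frame(band = levels(band),
                          n_bgcs = as.integer(table(band))),
       by_type = table(band, bgc$bgc_type),
       n_top_band_accessions = length(unique(bgc$mibig_hit[top & bgc$mibig_hit != ""])))
}

#' GCF distribution classes across Mash-clusters
#'
#' For every regrouped family with at least `min_bgcs` member BGCs, computes
#' the abundance per Mash-cluster (fraction of the cluster's genomes carrying
#' at least one member BGC) and classifies the family as `common` (present in
#' every cluster), `unique` (exactly one cluster), `accessory` (some but not
#' all), or `unassigned` (present only in genomes dropped from the
#' clustering). Genomes labeled `"Dropped"` are tallied separately, and
#' UpSet-style overlap counts of cluster presence patterns are emitted.
#'
#' @param regrouped a `regrouped_gcfs` object.
#' @param cluster_assignment data.frame (`genome_id`, `label`) with a
#'   Mash-cluster label or `"Dropped"` for every genome in the BGC table.
#' @param min_bgcs minimum member-BGC count for a family to be analyzed
#'   (default 5).
#' @return list with `families` (data.frame: `rgcf_id`, `known`, `n_bgcs`,
#'   `n_clusters_present`, `distribution_class`, `n_dropped_genomes`),
#'   `abundance` (family-by-cluster matrix of carrier fractions) and
#'   `overlap` (data.frame of presence patterns and family counts).
#' @export
cluster_distribution <- function(regrouped, cluster_assignment, min_bgcs = 5L) {
  bgc <- regrouped$bgc
  unknown <- setdiff(bgc$genome_id, cluster_assignment$genome_id)
  if (length(unknown)) stop("BGC table references genomes without a cluster ",
                            "label: ", paste(head(unknown, 5), collapse = ", "))
  lab <- setNames(cluster_assignment$label, cluster_assignment$genome_id)
  clusters <- setdiff(unique(cluster_assignment$label), "Dropped")
  clusters <- clusters[order(clusters)]
  cl_sizes <- table(factor(lab[lab != "Dropped"], levels = clusters))

  fams <- regrouped$families$rgcf_id[regrouped$families$n_bgcs >= min_bgcs]
  ab <- matrix(0, length(fams), length(clusters),
               dimnames = list(fams, clusters))
  n_dropped <- setNames(integer(length(fams)), fams)
  cls <- character(length(fams))
  for (i in seq_along(fams)) {
    carriers <- unique(bgc$genome_id[bgc$rgcf_id == fams[i]])
    cl <- lab[carriers]
    n_dropped[i] <- sum(cl == "Dropped")
    tab <- table(factor(cl[cl != "Dropped"], levels = clusters))
    ab[i, ] <- as.numeric(tab) / as.numeric(cl_sizes)
    present <- sum(tab > 0)
    cls[i] <- if (present == 0L) "unassigned"
      else if (present == length(clusters)) "common"
      else if (present == 1L) "unique" else "accessory"
  }
  pattern <- apply(ab > 0, 1L, function(x)
    if (!any(x)) "Dropped-only" else paste(clusters[x], collapse = "+"))
  overlap <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(overlap) <- c("pattern", "n_families")
  fam_df <- data.frame(rgcf_id = fams,
                       known = regrouped$families$known[match(fams, regrouped$families$rgcf_id)],
                       n_bgcs = regrouped$families$n_bgcs[match(fams, regrouped$families$rgcf_id)],
                       n_clusters_present = rowSums(ab > 0),
                       distribution_class = cls,
                       n_dropped_genomes = n_dropped,
                       row.names = NULL)
  list(families = fam_df, abundance = ab, overlap = overlap)
}
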