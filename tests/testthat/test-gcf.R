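bgc_row <- function(bgc_id, gcf, hit = "", sim = NA_real_, genome = "g1",
                    type = "terpene", start = 0) {
  data.frame(bgc_id = bgc_id, genome_id = genome, contig_id = "chr1",
             start = start, end = start + 1000, bgc_type = type,
             on_contig_edge = FALSE, gcf_id = gcf, mibig_hit = hit,
             kcb_similarity = sim)
}

test_that("known-GCF flagging is strict at 80% and uses majority accessions", {
  tab <- rbind(
    bgc_row("b1", "G1", "BGC01", 80.0),             # boundary: not known
    bgc_row("b2", "G2", "BGC01", 85, start = 2000),
    bgc_row("b3", "G2", "BGC01", 90, start = 4000),
    bgc_row("b4", "G2", "BGC01", 99, start = 6000),
    bgc_row("b5", "G2", "BGC02", 95, start = 8000), # minority accession
    bgc_row("b6", "G3", "", NA, start = 10000))
  flags <- flag_known_gcfs(tab)
  f <- setNames(flags$known, flags$gcf_id)
  expect_false(f[["G1"]])   # 80.0 is not above 80
  expect_true(f[["G2"]])
  expect_false(f[["G3"]])
  expect_equal(flags$mibig_accession[flags$gcf_id == "G2"], "BGC01")

  # tie on hit count: higher mean similarity wins, then smaller accession
  tie <- rbind(bgc_row("t1", "G4", "BGC09", 90),
               bgc_row("t2", "G4", "BGC03", 95, start = 2000))
  ft <- flag_known_gcfs(tie)
  expect_equal(ft$mibig_accession, "BGC03")
  tie2 <- rbind(bgc_row("u1", "G5", "BGC09", 90),
                bgc_row("u2", "G5", "BGC03", 90, start = 2000))
  expect_equal(flag_known_gcfs(tie2)$mibig_accession, "BGC03")
})

test_that("regrouping merges split known families and is idempotent", {
  # 3 known families each split into 2 labels + 2 unknown families
  rows <- list()
  for (k in 1:3) for (v in 1:2) {
    rows[[length(rows) + 1]] <- bgc_row(sprintf("b%d%d", k, v),
                                        sprintf("K%d_v%d", k, v),
                                        sprintf("BGC%03d", k), 90,
                                        genome = sprintf("g%d", v),
                                        start = k * 5000 + v)
  }
  rows[[7]] <- bgc_row("x1", "U1", start = 50000)
  rows[[8]] <- bgc_row("x2", "U2", "BGC999", 40, start = 60000)
  tab <- do.call(rbind, rows)
  rg <- regroup_gcfs(tab)
  expect_equal(sum(rg$families$known), 3)       # 6 split labels -> 3 families
  expect_equal(nrow(rg$families), 5)
  expect_lte(nrow(rg$families), nrow(rg$flags))
  # conservation: every BGC in exactly one regrouped family
  expect_false(anyNA(rg$bgc$rgcf_id))
  expect_equal(nrow(rg$bgc), nrow(tab))

  # idempotence: feeding back the regrouped labels changes nothing
  tab2 <- rg$bgc
  tab2$gcf_id <- tab2$rgcf_id
  rg2 <- regroup_gcfs(tab2[, names(tab)])
  expect_setequal(rg2$families$rgcf_id, rg$families$rgcf_id)
  expect_equal(sort(rg2$bgc$rgcf_id), sort(rg$bgc$rgcf_id))

  # identity when each accession is hit by exactly one GCF
  solo <- rbind(bgc_row("s1", "A", "BGC101", 95),
                bgc_row("s2", "B", "BGC102", 95, start = 2000))
  rgs <- regroup_gcfs(solo)
  expect_equal(nrow(rgs$families), 2)
})

test_that("a compound map merges same-compound accessions, and only then", {
  tab <- rbind(bgc_row("e1", "G1", "BGC0000853", 95),
               bgc_row("e2", "G2", "BGC0002052", 92, start = 2000),
               bgc_row("e3", "G3", "BGC0000100", 90, start = 4000))
  plain <- regroup_gcfs(tab)
  expect_equal(sum(plain$families$known), 3)   # entry-level: no merging
  cmap <- data.frame(accession = c("BGC0000853", "BGC0002052"),
                     compound = "ectoine")
  merged <- regroup_gcfs(tab, compound_map = cmap)
  expect_equal(sum(merged$families$known), 2)
  expect_true("RGCF_ectoine" %in% merged$families$rgcf_id)
})

test_that("regrouping collapses the generator's planted split families", {
  cfg <- simulation_config(seed = 13, genome_length = 1000)
  sim <- simulate_genomes(cfg)
  tab <- simulate_bgc_table(cfg, sim$truth)
  rg <- regroup_gcfs(tab$bgc)
  expect_equal(sum(rg$families$known), cfg$n_split_known_gcfs)
  # planted known fraction recovered exactly: every GCFK label flagged known
  flags <- rg$flags
  expect_true(all(flags$known[grepl("^GCFK", flags$gcf_id)]))
  expect_false(any(flags$known[!grepl("^GCFK", flags$gcf_id)]))
})

test_that("similarity bands conserve counts and spot the top-band accessions", {
  tab <- rbind(bgc_row("b1", "G1", "BGC01", 95),
               bgc_row("b2", "G1", "BGC02", 85, start = 2000),
               bgc_row("b3", "G2", "BGC03", 70, start = 4000),
               bgc_row("b4", "G2", "BGC04", 20, start = 6000),
               bgc_row("b5", "G3", "", NA, start = 8000))
  sb <- similarity_bands(tab)
  expect_equal(sum(sb$bands$n_bgcs), nrow(tab))
  expect_equal(sb$bands$n_bgcs, c(2L, 1L, 2L))   # <50 (incl. no-hit), 50-80, >80
  expect_equal(sb$n_top_band_accessions, 2)
  # all-empty similarities land in the lowest band
  none <- rbind(bgc_row("n1", "G1"), bgc_row("n2", "G2", start = 2000))
  expect_equal(similarity_bands(none)$bands$n_bgcs, c(2L, 0L, 0L))
  expect_error(similarity_bands(tab, breaks = c(0, 80, 50, 100)), "overlap")
})

test_that("distribution classes split common/accessory/unique exactly", {
  # 3 clusters x 2 genomes; families planted as 1 common, 1 accessory, 1 unique
  genomes <- sprintf("g%d", 1:6)
  clusters <- data.frame(genome_id = c(genomes, "g7"),
                         label = c(rep(c("M1", "M2", "M3"), each = 2), "Dropped"))
  rows <- list()
  add <- function(gcf, genome, start) bgc_row(paste0(gcf, "_", genome), gcf,
                                              genome = genome, start = start)
  for (g in genomes) rows[[length(rows) + 1]] <- add("COM", g, 0)
  for (g in genomes[1:4]) rows[[length(rows) + 1]] <- add("ACC", g, 5000)
  for (g in genomes[1:2]) rows[[length(rows) + 1]] <- add("UNI", g, 10000)
  rows[[length(rows) + 1]] <- add("COM", "g7", 0)   # dropped genome carrier
  # a small family below the min_bgcs threshold must be excluded
  rows[[length(rows) + 1]] <- add("TINY", "g1", 20000)
  tab <- do.call(rbind, rows)
  rg <- regroup_gcfs(tab)
  dist <- cluster_distribution(rg, clusters, min_bgcs = 2)
  cls <- setNames(dist$families$distribution_class, dist$families$rgcf_id)
  expect_equal(cls[["COM"]], "common")
  expect_equal(cls[["ACC"]], "accessory")
  expect_equal(cls[["UNI"]], "unique")
  expect_false("TINY" %in% names(cls))
  # abundance: fraction of the cluster's genomes carrying the family
  expect_equal(unname(dist$abundance["COM", ]), c(1, 1, 1))
  expect_equal(unname(dist$abundance["ACC", ]), c(1, 1, 0))
  expect_equal(dist$families$n_dropped_genomes[dist$families$rgcf_id == "COM"], 1)
  # classes partition the analyzed families
  expect_true(all(dist$families$distribution_class %in%
                    c("common", "accessory", "unique", "unassigned")))
  expect_error(cluster_distribution(rg, clusters[1:3, ], min_bgcs = 2),
               "without a cluster")
})

test_that("generator-planted distribution design is recovered end to end", {
  cfg <- simulation_config(seed = 41, genome_length = 1000)
  sim <- simulate_genomes(cfg)
  tab <- simulate_bgc_table(cfg, sim$truth)
  rg <- regroup_gcfs(tab$bgc)
  truth_clusters <- data.frame(
    genome_id = sim$truth$genome_id,
    label = ifelse(sim$truth$is_outlier, "Dropped", sim$truth$primary))
  dist <- cluster_distribution(rg, truth_clusters, min_bgcs = 5)
  cls <- setNames(dist$families$distribution_class, dist$families$rgcf_id)
  # split known families are planted in every genome -> common
  expect_true(all(cls[sprintf("RGCF_BGC%07d", seq_len(cfg$n_split_known_gcfs))]
                  == "common"))
  # unsplit backbone families are private to one primary cluster -> unique
  expect_true(all(cls[grepl("^GCF_P", names(cls))] == "unique"))
  # variable families: presence pattern decides the class, from the truth
  pres <- tab$planted$presence
  for (v in seq_len(cfg$n_variable_gcfs)) {
    fam <- sprintf("GCF_VAR%02d", v)
    prim_present <- unique(sub("_S.*", "", rownames(pres)[pres[, v]]))
    expected <- if (length(prim_present) == 0) NA_character_
      else if (length(prim_present) == cfg$n_primary) "common"
      else if (length(prim_present) == 1) "unique" else "accessory"
    if (!fam %in% names(cls)) next   # below min_bgcs or never inserted
    expect_equal(unname(cls[fam]), expected, info = fam)
  }
})
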