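# compact builder: one genome's ordered chromosome of families
chrom <- function(genome, fams, contig = "chr1", reversed = FALSE,
                  len = 1000, gap = 100) {
  n <- length(fams)
  starts <- (seq_len(n) - 1) * (len + gap)
  df <- data.frame(bgc_id = sprintf("%s.r%02d", genome, seq_len(n)),
                   genome_id = genome, contig_id = contig,
                   start = starts, end = starts + len,
                   bgc_type = "terpene", on_contig_edge = FALSE,
                   gcf_id = fams, mibig_hit = "", kcb_similarity = NA_real_,
                   rgcf_id = fams)
  if (reversed) {  # store the same chromosome in the opposite orientation
    total <- max(df$end) + gap
    s <- total - df$end; e <- total - df$start
    df$start <- s; df$end <- e
    df <- df[rev(seq_len(nrow(df))), ]
    df$bgc_id <- sprintf("%s.r%02d", genome, seq_len(n))
    rownames(df) <- NULL
  }
  df
}

test_that("BGC ordering sorts by contig and start with stable tie-breaks", {
  tab <- chrom("gA", c("f1", "f2", "f3"))
  shuffled <- tab[c(3, 1, 2), ]
  ord <- order_bgcs(shuffled)
  expect_equal(ord$gA$rgcf_id, c("f1", "f2", "f3"))
  expect_equal(ord$gA$position, 1:3)
  # reversing all coordinates reverses the order
  rev_tab <- chrom("gA", c("f1", "f2", "f3"), reversed = TRUE)
  ord_rev <- order_bgcs(rev_tab)
  expect_equal(ord_rev$gA$rgcf_id, c("f3", "f2", "f1"))
  # overlap warning path
  ov <- tab; ov$start[2] <- 500
  expect_warning(order_bgcs(ov), "overlapping")
})

test_that("the synteny graph carries one adjacency path per contig", {
  tab <- rbind(chrom("gA", c("f1", "f2", "f3")),
               chrom("gA", c("f4", "f5"), contig = "chr2"),
               chrom("gB", c("f1", "f2", "f3")))
  orders <- order_bgcs(tab)
  sg <- build_synteny_graph(orders)
  g <- sg$graph
  expect_equal(igraph::vcount(g), nrow(tab))
  adj <- igraph::E(g)[igraph::E(g)$type == "adjacency"]
  # sum over contigs of (n_bgcs - 1): (3-1) + (2-1) + (3-1)
  expect_equal(length(adj), 5)
  # co-membership cliques: identical genomes give a perfect matching
  sime <- igraph::E(g)[igraph::E(g)$type == "similarity"]
  expect_equal(length(sime), 3)   # f1, f2, f3 pairs across gA/gB
  # single genome, no shared families: path graph only
  solo <- build_synteny_graph(order_bgcs(chrom("gC", c("x1", "x2", "x3", "x4"))))
  expect_equal(igraph::ecount(solo$graph), 3)
  expect_true(all(igraph::E(solo$graph)$type == "adjacency"))
})

test_that("distance-list similarity edges respect the cutoff and id checks", {
  tab <- rbind(chrom("gA", c("f1", "f2")), chrom("gB", c("f1", "f2")))
  orders <- order_bgcs(tab)
  dl <- data.frame(bgc_a = c("gA.r01", "gA.r02"),
                   bgc_b = c("gB.r01", "gB.r02"),
                   distance = c(0.1, 0.5))
  sg <- build_synteny_graph(orders, similarity = dl, cutoff = 0.3)
  simed <- igraph::E(sg$graph)[igraph::E(sg$graph)$type == "similarity"]
  expect_equal(length(simed), 1)   # only the 0.1 pair survives
  bad <- data.frame(bgc_a = "nope", bgc_b = "gA.r01", distance = 0.1)
  expect_error(build_synteny_graph(orders, similarity = bad), "unknown BGCs")
})

test_that("a planted backbone is recovered, orientation-invariantly", {
  bb <- sprintf("B%d", 1:7)
  tab <- rbind(
    chrom("g1", c(bb[1:3], "v1", bb[4:7])),
    chrom("g2", c(bb[1:2], "v2", bb[3:7])),
    chrom("g3", bb, reversed = TRUE),
    chrom("g4", bb))
  orders <- order_bgcs(tab)
  res <- detect_backbone(orders)
  expect_equal(res$backbone, bb)
  expect_true(res$consistent)
  expect_equal(unname(res$orientation["g3"]), "reversed")
  expect_equal(unname(res$orientation["g1"]), "forward")
  expect_length(res$removed, 0)
  # invariance to genome input order
  res2 <- detect_backbone(orders[c("g3", "g1", "g4", "g2")])
  expect_equal(res2$backbone, res$backbone)
})

test_that("a single transposition excludes exactly the moved family", {
  bb <- sprintf("B%d", 1:7)
  moved <- c(bb[1:2], bb[4:6], bb[3], bb[7])   # B3 transposed in one genome
  tab <- rbind(chrom("g1", bb), chrom("g2", bb), chrom("g3", moved))
  res <- detect_backbone(order_bgcs(tab))
  expect_equal(res$removed, "B3")
  expect_equal(res$backbone, setdiff(bb, "B3"))
  expect_true(res$consistent)
})

test_that("variable regions return per-genome insertions in consensus orientation", {
  bb <- sprintf("B%d", 1:4)
  tab <- rbind(
    chrom("g1", c(bb[1:2], "insX", "insY", bb[3:4])),
    chrom("g2", bb),
    chrom("g3", c(bb[1:2], "insX", "insY", bb[3:4]), reversed = TRUE))
  orders <- order_bgcs(tab)
  res <- detect_backbone(orders)
  vr <- variable_regions(orders, res, anchors = c("B2", "B3"))
  expect_equal(vr$g1$rgcf_id, c("insX", "insY"))
  expect_equal(nrow(vr$g2), 0)                     # no insertions -> empty
  expect_equal(vr$g3$rgcf_id, c("insX", "insY"))   # reversal-invariant content
  expect_error(variable_regions(orders, res, anchors = c("B2", "nope")),
               "backbone")
  expect_warning(variable_regions(orders, res, anchors = c("B1", "B3")),
                 "not adjacent")
})

test_that("dot plots put self on the diagonal and reversal on the anti-diagonal", {
  fams <- sprintf("B%d", 1:6)
  a <- order_bgcs(chrom("gA", fams))$gA
  b <- order_bgcs(chrom("gB", fams, reversed = TRUE))$gB
  self <- dotplot_points(a, a)
  expect_equal(self$i, self$j)
  anti <- dotplot_points(a, b)
  expect_equal(anti$j[order(anti$i)], rev(seq_along(fams)))
  # only shared families produce points, monotonically for shared backbone
  c_ord <- order_bgcs(chrom("gC", c("B1", "u1", "B2", "B3", "u2")))$gC
  pts <- dotplot_points(a, c_ord)
  expect_equal(pts$family, c("B1", "B2", "B3"))
  expect_true(all(diff(pts$i) > 0) && all(diff(pts$j) > 0))
})

test_that("generator output recovers the planted backbone per primary cluster", {
  cfg <- simulation_config(seed = 19, genome_length = 1000)
  sim <- simulate_genomes(cfg)
  tab <- simulate_bgc_table(cfg, sim$truth)
  rg <- regroup_gcfs(tab$bgc)
  orders <- order_bgcs(rg$bgc)
  # oracle: planted backbone plus any variable family planted into *every*
  # secondary subcluster of the primary (those are conserved there too),
  # interleaved at their planted anchors
  conserved_oracle <- function(planted, p, cfg) {
    bb <- planted_backbone(planted, p)
    pres <- planted$presence
    secs <- grepl(paste0("^", p, "_"), rownames(pres))
    out <- character(0)
    for (b in seq_len(cfg$backbone_size)) {
      out <- c(out, bb[b])
      for (v in which(planted$anchor_after == b)) {
        if (all(pres[secs, v])) out <- c(out, sprintf("GCF_VAR%02d", v))
      }
    }
    out
  }
  for (p in unique(sim$truth$primary[!sim$truth$is_outlier])) {
    ids <- sim$truth$genome_id[!sim$truth$is_outlier & sim$truth$primary == p]
    res <- detect_backbone(orders[ids])
    expected <- conserved_oracle(tab$planted, p, cfg)
    # precision and recall both 1: recovered equals the planted conserved
    # set, in planted order, and contains the full 7-family backbone
    expect_equal(res$backbone, expected, info = p)
    expect_true(all(planted_backbone(tab$planted, p) %in% res$backbone))
    expect_true(res$consistent)
  }
})

test_that("synteny graph export round-trips through GraphML", {
  tab <- rbind(chrom("gA", c("f1", "f2")), chrom("gB", c("f1", "f2")))
  sg <- build_synteny_graph(order_bgcs(tab))
  prefix <- file.path(withr::local_tempdir(), "net")
  write_synteny_graph(sg, prefix)
  g2 <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(sg$graph))
  expect_equal(igraph::ecount(g2), igraph::ecount(sg$graph))
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"))
  expect_equal(nrow(nodes), 4)
})
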