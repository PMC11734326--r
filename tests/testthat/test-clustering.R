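test_that("feature rows expose correlation distance with degenerate-safe paths", {
  set.seed(21)
  D <- planted_matrix(c(4, 4), within = 0.01, between = 0.3)
  fr <- feature_rows(D)
  expect_identical(fr$features, D)
  block <- attr(D, "block")
  same <- outer(block, block, "==")
  ut <- upper.tri(D)
  expect_lt(mean(fr$cor_dist[same & ut]), mean(fr$cor_dist[!same & ut]))

  # same-block rows (identical up to their diagonal zeros) -> distance ~ 0
  D2 <- planted_matrix(c(3, 3), jitter = 0)
  fr2 <- feature_rows(D2)
  expect_lt(fr2$cor_dist[1, 2], 0.01)
  expect_gt(fr2$cor_dist[1, 4], 1.5)   # opposite blocks anticorrelate

  # 2-genome matrix: rows are constant up to the diagonal; degenerate-safe
  D3 <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_silent(fr3 <- feature_rows(D3))
  expect_equal(diag(fr3$cor_dist), c(a = 0, b = 0))

  # constant row triggers the warning path
  D4 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(feature_rows(D4), "constant")
})

test_that("choose_k recovers planted block counts and truncates k_range", {
  set.seed(22)
  D <- planted_matrix(c(6, 6, 6), within = 0.01, between = 0.3)
  ch <- choose_k(feature_rows(D)$features, D,
                 clustering_config(k_range = 2:8, n_init = 10))
  expect_equal(ch$k, 3)
  expect_equal(ari(ch$labels[, "3"], attr(D, "block")), 1)

  expect_warning(
    ch2 <- choose_k(feature_rows(D)$features, D,
                    clustering_config(k_range = 2:40, n_init = 5)),
    "truncated")
  expect_lte(max(ch2$k_range), nrow(D) - 1)
})

test_that("a homogeneous blob yields a flat, low silhouette curve", {
  set.seed(23)
  n <- 15
  D <- matrix(runif(n * n, 0.1, 0.12), n, n)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  dimnames(D) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  ch <- choose_k(feature_rows(D)$features, D,
                 clustering_config(k_range = 2:6, n_init = 10))
  expect_lt(max(ch$silhouette), 0.3)
  expect_true(ch$k %in% 2:6)
})

test_that("iterative clustering drops outliers and recovers the planted partition", {
  set.seed(24)
  D <- planted_matrix(c(8, 8, 8), within = 0.01, between = 0.3)
  block <- attr(D, "block")
  # add two far outliers, far from the blocks and from each other
  ids <- c(rownames(D), "out1", "out2")
  n <- length(ids)
  D2 <- matrix(0.9, n, n, dimnames = list(ids, ids))
  D2[1:24, 1:24] <- D
  D2["out1", 1:24] <- D2[1:24, "out1"] <- 0.6
  D2["out2", 1:24] <- D2[1:24, "out2"] <- 0.65
  diag(D2) <- 0
  res <- iterative_cluster(D2, clustering_config(k_range = 2:6, n_init = 10))
  asn <- setNames(res$assignment$label, res$assignment$genome_id)
  expect_setequal(names(asn)[asn == "Dropped"], c("out1", "out2"))
  retained <- asn[asn != "Dropped"]
  expect_equal(ari(retained, block[names(retained)]), 1)
  expect_equal(res$k, 3)
  # conservation: retained + dropped = input, disjoint
  expect_setequal(res$assignment$genome_id, ids)
  # final silhouettes of retained genomes all above the cutoff
  sil <- res$assignment$silhouette[res$assignment$label != "Dropped"]
  expect_true(all(sil >= 0.4))
})

test_that("a vacuous cutoff runs a single round and drops nothing", {
  set.seed(25)
  D <- planted_matrix(c(5, 5), within = 0.02, between = 0.2)
  res <- iterative_cluster(D, clustering_config(k_range = 2:4,
                                                silhouette_cutoff = -0.99,
                                                n_init = 5))
  expect_length(res$rounds, 1)
  expect_false(any(res$assignment$label == "Dropped"))
})

test_that("raising the cutoff never increases the retained count", {
  set.seed(26)
  D <- planted_matrix(c(6, 6), within = 0.05, between = 0.25, jitter = 0.05)
  retained <- sapply(c(0.1, 0.4, 0.6), function(cut) {
    res <- tryCatch(
      iterative_cluster(D, clustering_config(k_range = 2:5,
                                             silhouette_cutoff = cut,
                                             n_init = 10)),
      error = function(e) NULL)
    if (is.null(res)) 0 else sum(res$assignment$label != "Dropped")
  })
  expect_true(all(diff(retained) <= 0))
})

test_that("genome order only permutes labels", {
  set.seed(27)
  D <- planted_matrix(c(5, 5, 5), within = 0.01, between = 0.3)
  cfg <- clustering_config(k_range = 2:5, n_init = 20)
  res <- iterative_cluster(D, cfg)
  perm <- sample(rownames(D))
  res_p <- iterative_cluster(D[perm, perm], cfg)
  a <- setNames(res$assignment$label, res$assignment$genome_id)
  b <- setNames(res_p$assignment$label, res_p$assignment$genome_id)
  expect_equal(ari(a[names(b)], b), 1)
})

test_that("secondary clustering recovers planted subclusters with Mi_j labels", {
  set.seed(28)
  # 2 primary blocks x 3 subclusters x 4 genomes
  sub <- planted_matrix(c(4, 4, 4), within = 0.005, between = 0.04)
  n <- 24
  ids <- sprintf("g%02d", 1:n)
  D <- matrix(0.3 + runif(n * n, 0, 0.002), n, n, dimnames = list(ids, ids))
  D[1:12, 1:12] <- sub
  D[13:24, 13:24] <- sub
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  dimnames(D) <- list(ids, ids)
  diag(D) <- 0
  truth_prim <- rep(1:2, each = 12)
  truth_sec <- paste(truth_prim, rep(rep(1:3, each = 4), 2))
  cfg <- clustering_config(k_range = 2:6, n_init = 10)
  prim <- iterative_cluster(D, cfg)
  expect_equal(ari(prim$assignment$label, truth_prim), 1)
  sec <- secondary_cluster(D, prim$assignment, cfg)
  expect_equal(ari(sec$assignment$label, truth_sec), 1)
  expect_true(all(grepl("^M[0-9]+_[0-9]+$", sec$assignment$label)))
  expect_equal(length(unique(sec$assignment$label)), 6)
})

test_that("tiny or structureless primary clusters pass through unsplit", {
  set.seed(29)
  D <- planted_matrix(c(2, 10), within = 0.01, between = 0.3)
  asn <- data.frame(genome_id = rownames(D),
                    label = rep(c("M1", "M2"), c(2, 10)))
  expect_warning(expect_warning(
    sec <- secondary_cluster(D, asn, clustering_config(k_range = 2:4, n_init = 5)),
    "fewer than 3"), "no stable")
  expect_true(all(sec$assignment$label[1:2] == "M1_1"))
  expect_true("M1" %in% sec$unsplit)
  expect_setequal(sec$unsplit, c("M1", "M2"))
})

test_that("round table writer emits one cluster/silhouette column pair per round", {
  set.seed(30)
  D <- planted_matrix(c(4, 4), within = 0.01, between = 0.3)
  res <- iterative_cluster(D, clustering_config(k_range = 2:4, n_init = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_rounds(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 8)
  expect_true(all(c("genome_id", "cluster_round_1", "silhouette_round_1",
                    "final") %in% names(tab)))
})
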