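# Independent oracles used across tests. The k-mer oracle works on k-mer
# *strings* via Biostrings, never touching the package's C++ hashing path.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canonical_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  rc <- revcomp(kmers)
  unique(pmin(kmers, rc))
}

exact_jaccard <- function(seq_a, seq_b, k) {
  a <- canonical_kmer_set(seq_a, k)
  b <- canonical_kmer_set(seq_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

# Mash's Jaccard-to-distance transform applied to the exact Jaccard index
exact_mash_distance <- function(seq_a, seq_b, k) {
  j <- exact_jaccard(seq_a, seq_b, k)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / k)
}

# adjusted Rand index between two labelings, restricted to ids present in both
ari <- function(labels_a, labels_b) {
  stopifnot(requireNamespace("mclust", quietly = TRUE))
  mclust::adjustedRandIndex(labels_a, labels_b)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# planted block distance matrix: `sizes` blocks with the given within/between
# distances plus uniform jitter, symmetrized with zero diagonal
planted_matrix <- function(sizes, within = 0.01, between = 0.2, jitter = 0.002) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  D <- matrix(between, n, n) + matrix(runif(n * n, 0, jitter), n, n)
  same <- outer(block, block, "==")
  D[same] <- within + runif(sum(same), 0, jitter)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 0
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(D) <- list(ids, ids)
  attr(D, "block") <- setNames(block, ids)
  D
}
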