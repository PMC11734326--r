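#' MinHash sketch of a genome
#'
#' Computes the bottom-`s` sketch of hash values of the distinct canonical
#' k-mers of a genome (canonical = lexicographic minimum of a k-mer and its
#' reverse complement). Multiple sequences are treated as contigs of one
#' genome: k-mers are pooled across contigs and no k-mer spans a contig
#' boundary. The hash function is a fixed seeded 64-bit mix (truncated to 53
#' bits so values are exact doubles), so sketches are reproducible across
#' runs and platforms. Windows containing non-ACGT characters are skipped and
#' their count recorded.
#'
#' @param sequences character vector (or `Biostrings::DNAStringSet`) of contig
#'   sequences of one genome.
#' @param genome_id genome identifier stored in the sketch.
#' @param k k-mer length, 1..32 (default 21).
#' @param s sketch size: number of smallest hashes retained (default 1000).
#'   `Inf` keeps all distinct k-mer hashes (exact mode).
#' @return An object of class `mash_sketch`: list with `genome_id`, `k`, `s`,
#'   sorted `hashes`, `n_kmers` (valid windows) and `n_skipped`.
#' @export
sketch <- function(sequences, genome_id = "genome", k = 21L, s = 1000L) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("no sequences given")
  if (all(nchar(sequences) < k)) stop("sequence shorter than k")
  hashes <- numeric(0)
  n_kmers <- 0
  n_skipped <- 0
  for (sq in sequences) {
    if (nchar(sq) < k) next   # contig too short to contribute any k-mer
    h <- .kmer_hashes(sq, as.integer(k))
    hashes <- c(hashes, h$hashes)
    n_kmers <- n_kmers + h$n_kmers
    n_skipped <- n_skipped + h$n_skipped
  }
  hashes <- sort(unique(hashes))
  if (is.finite(s) && length(hashes) > s) hashes <- hashes[seq_len(s)]
  if (n_skipped > 0)
    message(genome_id, ": skipped ", n_skipped, " k-mer windows with non-ACGT bases")
  structure(list(genome_id = genome_id, k = as.integer(k), s = s,
                 hashes = hashes, n_kmers = n_kmers, n_skipped = n_skipped),
            class = "mash_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index `j` from the bottom-`s` sketch of the union of
#' the two hash sets (shared hashes / union size) and converts it to the Mash
#' distance `D = -log(2j / (1 + j)) / k`, which approximates per-base
#' substitution divergence (roughly `1 - ANI`). `j = 0` is capped at a
#' distance of 1, and distances never exceed 1.
#'
#' @param a,b `mash_sketch` objects with the same `k`.
#' @return Numeric distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "mash_sketch"), inherits(b, "mash_sketch"))
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  if (length(a$hashes) == 0L || length(b$hashes) == 0L)
    stop("empty sketch")
  s <- min(c(a$s, b$s, length(a$hashes) + length(b$hashes)))
  if (!is.finite(s)) s <- length(a$hashes) + length(b$hashes)
  res <- .sketch_shared(a$hashes, b$hashes, as.integer(s))
  j <- res$shared / res$union_size
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches list of `mash_sketch` objects sharing one `k`, with
#'   distinct genome ids.
#' @return Symmetric numeric matrix with zero diagonal, genome ids as
#'   dimnames.
#' @export
distance_matrix <- function(sketches) {
  if (length(sketches) < 2L) stop("need at least 2 sketches")
  ids <- vapply(sketches, function(x) x$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      d <- mash_distance(sketches[[i]], sketches[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Sketch every genome FASTA file in a set
#'
#' Each FASTA file holds one genome; multiple records are its contigs.
#'
#' @param paths named character vector of FASTA paths; names (or file
#'   basenames without extension) become genome ids.
#' @inheritParams sketch
#' @return list of `mash_sketch` objects.
#' @export
sketch_fasta_files <- function(paths, k = 21L, s = 1000L) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(paths))
  lapply(seq_along(paths), function(i) {
    sketch(Biostrings::readDNAStringSet(paths[i]), genome_id = ids[i], k = k, s = s)
  })
}

#' Read / write a square distance matrix as TSV
#'
#' The format has a header row of genome ids, a first column of genome ids
#' and a symmetric numeric body.
#'
#' @param path file path.
#' @return `read_distance_matrix()`: symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  D <- as.matrix(df)
  if (nrow(D) != ncol(D) || !all(rownames(D) == colnames(D)))
    stop("distance matrix must be square with matching row/column ids")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0) || any(D > 1)) stop("distances must be in [0, 1]")
  D
}

#' @rdname read_distance_matrix
#' @param D symmetric distance matrix with dimnames.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(genome_id = rownames(D), D, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
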