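#' Classify genome assembly quality (HQ / MQ / LQ)
#'
#' Applies the triage rules in this order: a genome with completeness <= 90%
#' or contamination >= 5% is LQ regardless of assembly level; otherwise
#' complete- or chromosome-level assemblies are HQ; otherwise scaffold/contig
#' assemblies with more than `max_contigs` contigs or N50 below `min_n50` are
#' LQ, and the rest are MQ. Thresholds follow the conventional cutoffs
#' (completeness > 90, contamination < 5, 100 contigs, 100 kb N50) and are
#' read strictly, e.g. exactly 100 contigs is still MQ.
#'
#' @param records data.frame with columns `genome_id`, `assembly_level` (one
#'   of complete/chromosome/scaffold/contig), `n_contigs`, `n50`,
#'   `completeness`, `contamination`.
#' @param min_completeness,max_contamination,max_contigs,min_n50 thresholds.
#' @return The input data.frame with a `quality_tier` column
#'   (`"HQ"`/`"MQ"`/`"LQ"`).
#' @export
classify_quality <- function(records,
                             min_completeness = 90,
                             max_contamination = 5,
                             max_contigs = 100,
                             min_n50 = 1e5) {
  required <- c("genome_id", "assembly_level", "n_contigs", "n50",
                "completeness", "contamination")
  for (f in required) {
    if (is.null(records[[f]])) stop("missing metadata column '", f, "'")
    if (anyNA(records[[f]])) stop("missing values in metadata column '", f, "'")
  }
  if (any(records$completeness < 0 | records$completeness > 100) ||
      any(records$contamination < 0 | records$contamination > 100))
    stop("completeness/contamination must be percentages in [0, 100]")
  if (any(records$n_contigs < 1)) stop("n_contigs must be >= 1")
  lvl <- tolower(records$assembly_level)
  if (!all(lvl %in% c("complete", "chromosome", "scaffold", "contig")))
    stop("assembly_level must be complete/chromosome/scaffold/contig")

  tier <- ifelse(records$completeness <= min_completeness |
                   records$contamination >= max_contamination, "LQ",
          ifelse(lvl %in% c("complete", "chromosome"), "HQ",
          ifelse(records$n_contigs > max_contigs | records$n50 < min_n50,
                 "LQ", "MQ")))
  records$quality_tier <- tier
  records
}

#' Select the analysis set of sufficiently good genomes
#'
#' @param records data.frame with a `quality_tier` column (see
#'   [classify_quality()]).
#' @return Character vector of genome ids with tier HQ or MQ, input order
#'   preserved.
#' @export
select_analysis_set <- function(records) {
  if (is.null(records$quality_tier)) stop("records are not classified yet")
  records$genome_id[records$quality_tier %in% c("HQ", "MQ")]
}

#' Read a genome metadata TSV
#'
#' Expected columns: `genome_id`, `assembly_level`, `n_contigs`, `n50`,
#' `completeness`, `contamination` and optionally `species_label` (empty for
#' genomes without a taxonomic assignment).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genome_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = NULL,
                   colClasses = NA)
  required <- c("genome_id", "assembly_level", "n_contigs", "n50",
                "completeness", "contamination")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata file lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(df$species_label)) df$species_label <- ""
  df$species_label[is.na(df$species_label)] <- ""
  df
}
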