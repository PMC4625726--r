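#' Classify a stop codon
#'
#' Mitochondrial protein genes either end on a complete stop codon
#' (`TAA`/`TAG`, or the mitochondrial `AGA`/`AGG`) or on an incomplete one
#' (`T` or `TA` at the gene boundary, written `T--` / `TA-`), which is
#' completed to `TAA` by polyadenylation of the transcript.
#'
#' @param stop_codon Character vector of stop annotations; `NA` or `"absent"`
#'   classify as `"none"`.
#' @return Character vector over `complete`, `incomplete`, `none`.
#' @examples
#' classify_stop(c("TAA", "T--", NA))
#' @export
classify_stop <- function(stop_codon) {
  x <- toupper(as.character(stop_codon))
  out <- rep(NA_character_, length(x))
  out[is.na(x) | x %in% c("", "ABSENT")] <- "none"
  out[x %in% c("TAA", "TAG", "AGA", "AGG")] <- "complete"
  out[x %in% c("T--", "TA-", "T", "TA")] <- "incomplete"
  if (anyNA(out))
    stop("unrecognized stop codon value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Per-feature lengths
#'
#' Adds `length_nt = end - start + 1` for every feature and, for CDS rows,
#' the encoded protein length: `length_nt/3 - 1` residues when the stop codon
#' is complete (the stop itself is not a residue), `floor(length_nt/3)` when
#' it is incomplete or absent.
#'
#' @param tab Annotation table.
#' @return The table with columns `length_nt`, `aa_length` (NA for
#'   non-coding features) and `stop_class` appended.
#' @export
feature_lengths <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab$length_nt <- tab$end - tab$start + 1L
  cds <- tab$feature_type == "CDS"
  if (any(cds & tab$length_nt < 6L))
    stop("CDS shorter than 6 nt: ",
         paste(tab$name[cds & tab$length_nt < 6L], collapse = ", "))
  tab$stop_class <- NA_character_
  tab$stop_class[cds] <- classify_stop(tab$stop_codon[cds])
  tab$aa_length <- NA_integer_
  complete <- cds & tab$stop_class == "complete"
  if (any(complete & tab$length_nt %% 3L != 0L))
    stop("complete-stop CDS with length not a multiple of 3: ",
         paste(tab$name[complete & tab$length_nt %% 3L != 0L], collapse = ", "))
  tab$aa_length[complete] <- tab$length_nt[complete] %/% 3L - 1L
  other <- cds & !complete
  tab$aa_length[other] <- tab$length_nt[other] %/% 3L
  tab
}

#' Signed intergenic gaps
#'
#' The gap attributed to each feature is the number of nucleotides between
#' its start and the end of the preceding feature in the table:
#' `start(i) - end(i-1) - 1`. Negative values are overlaps and are reported
#' as such, never clipped. The first feature's gap is computed circularly
#' from the last feature's end across the origin.
#'
#' @param tab Annotation table sorted by start.
#' @param genome_length Length of the circular genome (bp).
#' @return Integer vector of signed gaps, one per feature (in table order).
#' @export
intergenic_gaps <- function(tab, genome_length) {
  tab <- as.data.frame(tab)
  if (is.unsorted(tab$start))
    stop("annotation table must be sorted by start coordinate")
  n <- nrow(tab)
  if (n == 0L) return(integer(0))
  prev_end <- c(tab$end[n] - as.integer(genome_length), tab$end[-n])
  as.integer(tab$start - prev_end - 1L)
}

#' z-score of a tRNA length against a reference set
#'
#' @param query_length Query length (bp).
#' @param reference_lengths Numeric vector of reference tRNA lengths
#'   (length >= 2, non-constant).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1). The choice is a documented convention.
#' @return The z-score `(query - mean) / sd`.
#' @export
trna_length_zscore <- function(query_length, reference_lengths,
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.numeric(reference_lengths)
  if (length(x) < 2L) stop("reference set must contain at least 2 lengths")
  m <- mean(x)
  v <- sum((x - m)^2) / if (sd_type == "population") length(x) else length(x) - 1L
  if (v == 0) stop("reference lengths have zero variance")
  (as.numeric(query_length) - m) / sqrt(v)
}

#' Annotation summary
#'
#' Derived per-feature statistics (lengths, protein lengths, stop classes,
#' signed intergenic gaps) plus genome-level tallies: feature counts per type
#' and strand, control-region length, and the genome span implied by the
#' annotation. For a gap-consistent circular annotation the feature lengths
#' and signed gaps sum to the genome length.
#'
#' @param tab Annotation table.
#' @param genome_length Genome length; defaults to `max(end)`.
#' @return List with `features` (the augmented table, including an
#'   `intergenic_gap` column) and `genome` (named list of genome-level
#'   statistics).
#' @export
annotation_summary <- function(tab, genome_length = NULL) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (is.null(genome_length)) genome_length <- max(tab$end)
  feats <- feature_lengths(tab)
  feats$intergenic_gap <- intergenic_gaps(tab, genome_length)
  cr <- feats$feature_type == "CR"
  genome <- list(
    genome_length = as.integer(genome_length),
    n_features = nrow(feats),
    n_cds = sum(feats$feature_type == "CDS"),
    n_trna = sum(feats$feature_type == "tRNA"),
    n_rrna = sum(feats$feature_type == "rRNA"),
    n_cr = sum(cr),
    n_h_strand = sum(feats$strand == "H"),
    n_l_strand = sum(feats$strand == "L"),
    control_region_length = if (any(cr)) as.integer(sum(feats$length_nt[cr])) else NA_integer_,
    length_plus_gaps = as.integer(sum(feats$length_nt) + sum(feats$intergenic_gap))
  )
  list(features = feats, genome = genome)
}
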