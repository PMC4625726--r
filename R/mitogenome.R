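#' Circular mitogenome container
#'
#' Bundles an H-strand nucleotide sequence with an ordered gene annotation
#' table. Coordinates are 1-based fully closed intervals on the H strand; a
#' feature crossing the origin of the circle is stored with `end > length`
#' and normalized on access.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (H strand).
#' @param annotations Annotation data frame as returned by
#'   [read_annotation_table()], or `NULL`.
#' @param name Optional sequence name (used when writing FASTA).
#' @return Object of class `mitogenome`: a list with elements `sequence`,
#'   `length`, `is_circular` (always `TRUE`), `annotations`, `name`.
#' @export
mitogenome <- function(sequence, annotations = NULL, name = "mitogenome") {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence contains characters outside A,C,G,T,N")
  len <- nchar(sequence)
  if (len < 1L) stop("empty sequence")
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    if (any(((annotations$start - 1L) %% len) + 1L != annotations$start))
      stop("annotation start coordinates outside [1, genome length]")
  }
  structure(
    list(sequence = sequence, length = len, is_circular = TRUE,
         annotations = annotations, name = name),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %d bp (circular), %s annotated features\n",
              x$name, x$length,
              if (is.null(x$annotations)) "no" else nrow(x$annotations)))
  invisible(x)
}

ANNOT_COLS <- c("name", "start", "end", "strand", "feature_type",
                "start_codon", "stop_codon")
FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "CR")

validate_annotations <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  missing <- setdiff(c("name", "start", "end", "strand", "feature_type"),
                     names(tab))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("start_codon", "stop_codon"))
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  tab <- tab[ANNOT_COLS]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(is.na(tab$start)) || any(is.na(tab$end)) ||
      any(tab$start < 1L) || any(tab$end < 1L))
    stop("start/end must be positive integers")
  if (any(tab$end < tab$start))
    stop("end < start; features crossing the origin must be stored with end > genome length")
  bad <- setdiff(unique(tab$strand), c("H", "L"))
  if (length(bad)) stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$feature_type), FEATURE_TYPES)
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  for (col in c("start_codon", "stop_codon")) {
    tab[[col]] <- as.character(tab[[col]])
    tab[[col]][!is.na(tab[[col]]) & tab[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(tab$name))
    stop("duplicate feature name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  cds <- tab$feature_type == "CDS"
  if (any(cds & is.na(tab$start_codon)))
    stop("CDS feature(s) without a start codon")
  trna_len <- tab$end - tab$start + 1L
  bad <- tab$feature_type == "tRNA" & (trna_len < 50L | trna_len > 100L)
  if (any(bad))
    stop("tRNA length outside [50, 100] bp: ", paste(tab$name[bad], collapse = ", "))
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a gene annotation table
#'
#' Reads a TSV with header columns `name start end strand feature_type
#' start_codon stop_codon` (the last two may be empty for non-coding
#' features). Coordinates are 1-based closed intervals on the H strand;
#' strand is `H` or `L`. Rows are returned sorted by start coordinate.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations (classes `gene_annotation`,
#'   `data.frame`), sorted by `start`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  if (length(readLines(path, n = 2L, warn = FALSE)) < 2L) {
    tab <- data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), feature_type = character(),
                      start_codon = character(), stop_codon = character(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", fill = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    tab <- validate_annotations(tab)
  }
  class(tab) <- c("gene_annotation", "data.frame")
  tab
}

#' Write a gene annotation table
#'
#' @param tab Annotation data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[ANNOT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Bundled Austrolebias charrua annotation (GenBank KP718940)
#'
#' The published annotation of the A. charrua reference mitogenome
#' (17,271 bp): 13 protein-coding genes, 22 tRNAs, 2 rRNAs and the control
#' region, with start/stop codons and strand assignments.
#'
#' @return Annotation data frame (see [read_annotation_table()]).
#' @export
charrua_annotation <- function() {
  read_annotation_table(system.file("extdata", "KP718940_annotation.tsv",
                                    package = "mitoasym", mustWork = TRUE))
}

#' Published sibling heteroplasmy support table
#'
#' Per-sample read support (`alt_reads`/`total_reads`) for the variant sites
#' reported in three A. charrua full siblings (AUS4, AUS5 and the reference
#' individual AUS7), mapped against the KP718940 reference.
#'
#' @return Data frame with columns `position, gene, sample, ref, alt,
#'   alt_reads, total_reads`.
#' @export
sibling_variant_support <- function() {
  utils::read.delim(system.file("extdata", "KP718940_sibling_variants.tsv",
                                package = "mitoasym", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Read / write FASTA
#'
#' Thin wrappers around seqinr for single-sequence genome FASTA files and
#' multi-sequence gene sets.
#'
#' @param path FASTA path.
#' @return `read_fasta()` returns a named character vector of uppercase
#'   sequences; `read_genome_fasta()` returns a [mitogenome()] built from the
#'   first sequence.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, as.character, character(1))),
                  names(seqs))
}

#' @rdname read_fasta
#' @param annotations Optional annotation table to attach.
#' @export
read_genome_fasta <- function(path, annotations = NULL) {
  seqs <- read_fasta(path)
  mitogenome(seqs[[1L]], annotations = annotations, name = names(seqs)[1L])
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences (or a `mitogenome`).
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "mitogenome"))
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Extract the coding-strand sequence of an annotated feature
#'
#' H-strand features return `sequence[start..end]`; L-strand features return
#' the reverse complement, i.e. the feature read 5'->3' on its coding strand.
#' Features stored with `end > length` wrap across the origin of the circle.
#'
#' @param genome A [mitogenome()].
#' @param feature A single annotation row (data frame or list with `start`,
#'   `end`, `strand`).
#' @return Nucleotide string.
#' @export
extract_gene_sequence <- function(genome, feature) {
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  len <- genome$length
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid feature coordinates")
  if (start > len)
    stop("feature start beyond genome length after normalization")
  if (end - start + 1L > len)
    stop("feature longer than the genome")
  idx <- ((seq.int(start, end) - 1L) %% len) + 1L
  chars <- strsplit(genome$sequence, "")[[1L]][idx]
  s <- paste(chars, collapse = "")
  if (identical(feature$strand, "L")) reverse_complement(s) else s
}

#' Map a mitogenome coordinate to a codon within a CDS
#'
#' For an H-strand gene, `gene_pos = pos - start + 1`; for an L-strand gene
#' the coding strand runs the other way, so `gene_pos = end - pos + 1`. The
#' codon index is `ceiling(gene_pos / 3)` (1-based) and the offset is the
#' position within the codon (1, 2 or 3).
#'
#' @param feature A single CDS annotation row.
#' @param pos 1-based H-strand coordinate.
#' @param genome_length Optional genome length, needed only for features
#'   wrapping across the origin (stored with `end > genome_length`).
#' @return List with `codon_index` and `offset`.
#' @examples
#' nd2 <- list(name = "ND2", start = 4041L, end = 5085L, strand = "H",
#'             feature_type = "CDS")
#' position_to_codon(nd2, 4105)  # codon 22, offset 2
#' @export
position_to_codon <- function(feature, pos, genome_length = NULL) {
  if (!identical(feature$feature_type, "CDS"))
    stop("position_to_codon requires a CDS feature")
  pos <- as.integer(pos)
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  if (!is.null(genome_length) && end > genome_length && pos < start)
    pos <- pos + as.integer(genome_length)  # wrap-around feature
  if (pos < start || pos > end)
    stop("position ", pos, " outside feature ", feature$name,
         " [", start, ", ", end, "]")
  gene_pos <- if (identical(feature$strand, "L")) end - pos + 1L else pos - start + 1L
  list(codon_index = as.integer(ceiling(gene_pos / 3)),
       offset = as.integer(((gene_pos - 1L) %% 3L) + 1L))
}

#' Locate the CDS feature(s) containing a position
#'
#' @param annotations Annotation table.
#' @param pos 1-based coordinate.
#' @param genome_length Optional, for wrap-around features.
#' @return Data frame of the CDS rows covering `pos` (possibly empty, or
#'   several rows where genes overlap).
#' @export
cds_at_position <- function(annotations, pos, genome_length = NULL) {
  tab <- as.data.frame(annotations)
  cds <- tab[tab$feature_type == "CDS", , drop = FALSE]
  p <- as.integer(pos)
  hit <- cds$start <= p & cds$end >= p
  if (!is.null(genome_length)) {
    wrap <- cds$end > genome_length
    hit <- hit | (wrap & (p + genome_length) <= cds$end)
  }
  cds[hit, , drop = FALSE]
}

#' Minimal GenBank flat-file reader
#'
#' Extracts CDS, tRNA, rRNA and D-loop features (coordinates, strand from
#' `complement(...)`, gene/product names) and the ORIGIN sequence from a
#' GenBank flat file, mapping them onto the annotation-table model. Joined
#' locations and qualifier-derived start/stop codons are not supported; the
#' D-loop is mapped to feature type `CR`.
#'
#' @param path Path to a GenBank flat file.
#' @return A [mitogenome()] with the parsed annotation attached.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (!length(feat_start) || !length(origin))
    stop("not a GenBank flat file (missing FEATURES/ORIGIN): ", path)
  seq_lines <- lines[(origin[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))

  keys <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", `D-loop` = "CR")
  rows <- list()
  i <- feat_start[1L] + 1L
  while (i < origin[1L]) {
    m <- regmatches(lines[i],
                    regexec("^\\s{5}(\\S+)\\s+(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?",
                            lines[i]))[[1L]]
    if (length(m) && m[2L] %in% names(keys)) {
      key <- m[2L]
      strand <- if (nzchar(m[3L])) "L" else "H"
      start <- as.integer(m[4L]); end <- as.integer(m[5L])
      name <- NA_character_
      j <- i + 1L
      while (j < origin[1L] && grepl("^\\s{10,}", lines[j]) &&
             !grepl("^\\s{5}\\S", lines[j])) {
        q <- regmatches(lines[j], regexec("/(gene|product)=\"([^\"]+)\"", lines[j]))[[1L]]
        if (length(q) && (is.na(name) || q[2L] == "gene")) name <- q[3L]
        j <- j + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = if (is.na(name)) paste0(key, "_", start) else name,
        start = start, end = end, strand = strand,
        feature_type = keys[[key]],
        start_codon = if (key == "CDS") substr(
          if (strand == "H") substr(sequence, start, start + 2L)
          else reverse_complement(substr(sequence, end - 2L, end)), 1L, 3L)
          else NA_character_,
        stop_codon = NA_character_, stringsAsFactors = FALSE)
      i <- j
    } else i <- i + 1L
  }
  tab <- do.call(rbind, rows)
  mitogenome(sequence, annotations = tab,
             name = sub("^LOCUS\\s+(\\S+).*", "\\1", lines[1L]))
}
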