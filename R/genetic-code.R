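#' Genetic code tables
#'
#' Returns a genetic code as a named character vector mapping the 64 codons
#' (DNA alphabet, e.g. `"ATG"`) to one-letter amino acids, with `"*"` for
#' stop. The default is the vertebrate mitochondrial code (NCBI translation
#' table 2), under which `ATA` encodes Met, `TGA` encodes Trp and `AGA`/`AGG`
#' are stop codons. The standard code (table 1) is available for comparison.
#'
#' @param id Integer code identifier: `2` (vertebrate mitochondrial, default)
#'   or `1` (standard).
#' @return Named character vector of length 64 with attribute `id`.
#' @examples
#' code <- genetic_code()
#' code[["ATA"]]  # "M"
#' code[["TGA"]]  # "W"
#' @export
genetic_code <- function(id = 2L) {
  id <- as.integer(id)
  aa <- switch(as.character(id),
    "1" = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "2" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
    stop("unsupported genetic code id: ", id)
  )
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(vapply(bases, function(b1)
    vapply(bases, function(b2) paste0(b1, b2, bases), character(4)),
    character(16)))
  tab <- stats::setNames(strsplit(aa, "")[[1]], codons)
  attr(tab, "id") <- id
  tab
}

#' @rdname genetic_code
#' @param code A genetic code vector from [genetic_code()].
#' @param codon A 3-letter codon string (DNA alphabet).
#' @return For `is_stop_codon()`, a logical.
#' @export
is_stop_codon <- function(codon, code = genetic_code()) {
  !is.na(code[codon]) & code[codon] == "*"
}

# Three-letter amino-acid names used in effect reports ("Phe to Leu" etc.)
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "STOP", X = "Xaa"
)

#' Three-letter amino-acid name
#'
#' @param aa One-letter amino-acid code(s); `"*"` maps to `"STOP"`.
#' @return Character vector of three-letter names.
#' @export
aa_three_letter <- function(aa) {
  out <- AA_THREE[aa]
  out[is.na(out)] <- "Xaa"
  unname(out)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes other than N are not supported; N maps to N.
#'
#' @param seq Nucleotide string (or vector of strings) over `A,C,G,T,N`,
#'   case-insensitive.
#' @return Reverse-complemented string(s), uppercase.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) stop("sequence shorter than one codon")
  starts <- seq(1L, n - 2L, by = 3L)
  substring(cds, starts, starts + 2L)
}

#' Translate a coding sequence
#'
#' Translates an in-frame coding sequence (already on the coding strand)
#' under a genetic code. A terminal stop codon is excluded from the returned
#' peptide; internal stops are retained as `"*"` and their codon indices are
#' reported in the `internal_stops` attribute rather than silently dropped.
#' Codons containing characters outside `A,C,G,T` (including N) translate to
#' `"X"`.
#'
#' Many mitochondrial genes end on an incomplete stop codon (a trailing `T`
#' or `TA` completed to `TAA` by polyadenylation of the transcript). With
#' `incomplete_stop = TRUE` the trailing 1-2 nucleotides are ignored and
#' every complete codon is translated.
#'
#' @param cds Nucleotide string, length >= 3.
#' @param code Genetic code from [genetic_code()].
#' @param incomplete_stop Logical; if `TRUE`, a trailing partial codon is
#'   dropped instead of raising a frame error.
#' @return Amino-acid string; attribute `internal_stops` holds the 1-based
#'   codon indices of any internal stop codons (integer(0) if none).
#' @examples
#' translate_cds("ATGTTTTAA")             # "MF"
#' translate_cds("ATA")                   # "M" under the mitochondrial code
#' @export
translate_cds <- function(cds, code = genetic_code(), incomplete_stop = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence must be at least 3 nt")
  rem <- n %% 3L
  if (rem != 0L) {
    if (!incomplete_stop)
      stop("sequence length ", n, " is not a multiple of 3 (set incomplete_stop = TRUE to drop trailing bases)")
    cds <- substr(cds, 1L, n - rem)
  }
  codons <- split_codons(cds)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or other non-ACGT characters
  k <- length(aa)
  terminal_stop <- aa[k] == "*"
  if (terminal_stop) aa <- aa[-k]
  internal <- which(aa == "*")
  out <- paste(aa, collapse = "")
  attr(out, "internal_stops") <- as.integer(internal)
  out
}
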