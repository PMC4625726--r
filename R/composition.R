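#' Base composition and strand skews
#'
#' Computes base fractions over the called bases (N excluded from all
#' denominators), G+C content and the strand-asymmetry skews
#' `GCskew = (G - C) / (G + C)` and `ATskew = (A - T) / (A + T)`, computed on
#' the strand supplied. A negative GC skew indicates an excess of C over G on
#' that strand. Note that some literature uses the opposite sign convention
#' (C - G); this package fixes the convention above.
#'
#' @param seq Nucleotide string (case-insensitive).
#' @return Object of class `composition_profile`: list with `n` (called
#'   bases), `fA`, `fC`, `fG`, `fT`, `gc`, `gc_skew`, `at_skew`. A skew whose
#'   denominator is zero is `NA` and flagged in `skew_defined`.
#' @examples
#' composition("GGGC")$gc_skew  # 0.5
#' @export
composition <- function(seq) {
  counts <- base_counts(seq)
  n <- sum(counts)
  if (n == 0L) stop("sequence has no called (non-N) bases")
  f <- counts / n
  gc <- f[["G"]] + f[["C"]]
  at <- f[["A"]] + f[["T"]]
  structure(
    list(n = n,
         fA = f[["A"]], fC = f[["C"]], fG = f[["G"]], fT = f[["T"]],
         gc = gc,
         gc_skew = if (gc > 0) (f[["G"]] - f[["C"]]) / gc else NA_real_,
         at_skew = if (at > 0) (f[["A"]] - f[["T"]]) / at else NA_real_,
         skew_defined = c(gc = gc > 0, at = at > 0)),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition> n=%d A=%.3f C=%.3f G=%.3f T=%.3f GC=%.3f GCskew=%.3f ATskew=%.3f\n",
              x$n, x$fA, x$fC, x$fG, x$fT, x$gc, x$gc_skew, x$at_skew))
  invisible(x)
}

base_counts <- function(seq) {
  chars <- strsplit(toupper(paste(seq, collapse = "")), "")[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("unexpected characters in sequence: ", paste(bad, collapse = ", "))
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  stats::setNames(as.integer(tab), names(tab))
}

# Trim a CDS to complete codons and optionally drop a terminal stop codon.
# Trailing 1-2 nt (incomplete stop) are always dropped; codons containing
# N (or gaps) are excluded from counts by the callers below.
prepare_codons <- function(cds, code, drop_stops = TRUE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  cds <- substr(cds, 1L, n - (n %% 3L))
  codons <- split_codons(cds)
  k <- length(codons)
  if (drop_stops && !is.na(code[codons[k]]) && code[codons[k]] == "*")
    codons <- codons[-k]
  codons
}

#' Codon-position composition profile
#'
#' Tallies base composition separately at codon positions 1, 2 and 3 over
#' the concatenation of a set of in-frame coding sequences (supplied on
#' their coding strand). `GC1`, `GC2`, `GC3` are reported in percent and the
#' overall coding G+C as a fraction, following the mixed units conventional
#' in mitogenome composition tables. Trailing incomplete codons are dropped;
#' terminal stop codons are excluded by default; codons containing N are
#' excluded entirely.
#'
#' By default the profile is computed on raw concatenated CDS. Aligned input
#' (with `-` gap characters) is accepted behind `gaps_ok = TRUE`, in which
#' case codons containing gaps are excluded like N codons.
#'
#' @param cds_set Character vector (or list) of in-frame coding sequences.
#' @param code Genetic code used to recognize stop codons.
#' @param drop_stops Drop a terminal complete stop codon from each CDS.
#' @param gaps_ok Accept `-` characters (alignment columns).
#' @return Object of class `codon_position_profile`: list with `counts`
#'   (3 x 4 matrix of base counts by codon position), `fractions`, `gc_percent`
#'   (named `GC1`,`GC2`,`GC3`), `coding_gc` (fraction), `n_codons`.
#' @export
codon_position_profile <- function(cds_set, code = genetic_code(),
                                   drop_stops = TRUE, gaps_ok = FALSE) {
  cds_set <- vapply(cds_set, as.character, character(1))
  counts <- matrix(0L, nrow = 3L, ncol = 4L,
                   dimnames = list(position = c("1", "2", "3"),
                                   base = c("A", "C", "G", "T")))
  n_codons <- 0L
  for (cds in cds_set) {
    codons <- prepare_codons(cds, code, drop_stops = drop_stops)
    if (!gaps_ok && any(grepl("-", codons, fixed = TRUE)))
      stop("gap characters present; set gaps_ok = TRUE for aligned input")
    keep <- grepl("^[ACGT]{3}$", codons)
    codons <- codons[keep]
    if (!length(codons)) next
    n_codons <- n_codons + length(codons)
    for (p in 1:3) {
      b <- substr(codons, p, p)
      tab <- table(factor(b, levels = c("A", "C", "G", "T")))
      counts[p, ] <- counts[p, ] + as.integer(tab)
    }
  }
  if (n_codons == 0L) stop("no complete ACGT codons in input")
  fractions <- counts / rowSums(counts)
  gcp <- 100 * (fractions[, "G"] + fractions[, "C"])
  structure(
    list(counts = counts, fractions = fractions,
         gc_percent = stats::setNames(as.numeric(gcp), c("GC1", "GC2", "GC3")),
         coding_gc = sum(counts[, c("G", "C")]) / sum(counts),
         n_codons = n_codons),
    class = "codon_position_profile"
  )
}

#' Codon usage table
#'
#' Counts each of the 64 codons over a set of in-frame coding sequences.
#' Terminal stop codons are excluded unless `count_stops = TRUE`; trailing
#' incomplete codons are always dropped; codons containing N are excluded.
#'
#' @inheritParams codon_position_profile
#' @param count_stops Count terminal stop codons as well.
#' @return Object of class `codon_usage`: named integer vector of length 64
#'   (codon order T/C/A/G nested), with the genetic code attached as
#'   attribute `code`.
#' @export
codon_usage <- function(cds_set, code = genetic_code(), count_stops = FALSE) {
  usage <- stats::setNames(integer(length(code)), names(code))
  for (cds in cds_set) {
    codons <- prepare_codons(cds, code, drop_stops = !count_stops)
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    if (!length(codons)) next
    tab <- table(factor(codons, levels = names(code)))
    usage <- usage + as.integer(tab)
  }
  structure(usage, code = code, class = c("codon_usage", class(usage)))
}

#' Amino-acid usage from a codon usage table
#'
#' Marginalizes codon counts over the synonymous families of the attached
#' genetic code; the stop "family" is reported under `"*"`.
#'
#' @param usage A [codon_usage()] table.
#' @return Named integer vector of amino-acid counts.
#' @export
amino_acid_usage <- function(usage) {
  code <- attr(usage, "code")
  tapply(as.integer(usage), code[names(usage)], sum)
}

#' Relative synonymous codon usage
#'
#' RSCU for each codon: observed count divided by the mean count of its
#' synonymous family. Stop codons get `NA`.
#'
#' @param usage A [codon_usage()] table.
#' @return Named numeric vector of RSCU values.
#' @export
rscu <- function(usage) {
  code <- attr(usage, "code")
  aa <- code[names(usage)]
  out <- rep(NA_real_, length(usage))
  names(out) <- names(usage)
  for (a in setdiff(unique(aa), "*")) {
    fam <- names(usage)[aa == a]
    m <- mean(usage[fam])
    out[fam] <- if (m > 0) usage[fam] / m else NA_real_
  }
  out
}

#' Remove one codon position from a codon alignment
#'
#' Drops every alignment column belonging to the chosen codon position
#' (used e.g. to strip saturated third positions before phylogenetic
#' re-inference). Gap characters are allowed. The result is no longer a
#' translatable codon alignment, so no translation is offered on it.
#'
#' @param alignment Character vector of aligned sequences, all the same
#'   width, width a multiple of 3.
#' @param position Codon position to remove: 1, 2 or 3.
#' @return Character vector of sequences of width `2/3` the input width
#'   (names preserved).
#' @export
strip_codon_position <- function(alignment, position = 3L) {
  position <- as.integer(position)
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment sequences differ in width")
  if (w %% 3L != 0L) stop("alignment width ", w, " is not a multiple of 3")
  drop <- seq.int(position, w, by = 3L)
  keep <- setdiff(seq_len(w), drop)
  out <- vapply(alignment, function(s)
    paste(strsplit(s, "")[[1L]][keep], collapse = ""), character(1))
  names(out) <- names(alignment)
  out
}

#' Spearman rank correlation
#'
#' Spearman's rho with midranks for ties and, for small samples without
#' ties, the exact permutation p-value (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = !ties))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
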