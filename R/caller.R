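#' Heteroplasmy caller parameters
#'
#' Thresholds of the filter cascade. Defaults mirror a deep-coverage
#' mitochondrial design: at least 20x gated coverage, an alternative base
#' seen in at least two clean reads with at least one read on each mapping
#' strand, Phred 30 base and mapping quality gates, supporting observations
#' at least 5 bp from both read ends, and reference-matching flanks within
#' +/- 5 bp on the supporting reads. The 5 bp read-end distance and the
#' +/- 5 bp neighborhood window quantify qualitative filter descriptions and
#' are configurable assumptions.
#'
#' @param min_coverage Minimum gated depth at the site.
#' @param min_alt_reads Minimum clean supporting reads for the alternative.
#' @param require_both_strands Require support on both mapping strands.
#' @param min_base_quality,min_mapping_quality Phred quality gates applied
#'   to observations before any counting.
#' @param min_read_end_distance Minimum distance (bp) of a supporting
#'   observation from both read ends; observations with unknown distances
#'   pass.
#' @param neighborhood_window Half-width (bp) of the flank window in which a
#'   supporting read must match the reference.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 20L, min_alt_reads = 2L,
                          require_both_strands = TRUE,
                          min_base_quality = 30L, min_mapping_quality = 30L,
                          min_read_end_distance = 5L,
                          neighborhood_window = 5L) {
  p <- list(min_coverage = as.integer(min_coverage),
            min_alt_reads = as.integer(min_alt_reads),
            require_both_strands = isTRUE(require_both_strands),
            min_base_quality = as.integer(min_base_quality),
            min_mapping_quality = as.integer(min_mapping_quality),
            min_read_end_distance = as.integer(min_read_end_distance),
            neighborhood_window = as.integer(neighborhood_window),
            max_alt_alleles = 1L)
  if (any(unlist(p[c(1, 2, 4, 5, 6, 7)]) < 0L))
    stop("caller thresholds must be >= 0")
  class(p) <- "caller_params"
  p
}

# Positions at which each read mismatches the reference (any quality),
# used by the neighborhood filter. Deletion placeholders count as dirty.
read_mismatch_index <- function(obs) {
  mm <- obs[obs$base != obs$ref, c("read_id", "pos")]
  split(mm$pos, mm$read_id)
}

#' Evaluate one pileup column against the filter cascade
#'
#' A candidate variant is emitted only when: gated coverage >= `min_coverage`;
#' there is a single alternative nucleotide (two distinct alternatives each
#' backed by the minimal two-read evidence level reject the site as
#' multiallelic); and the alternative is supported by at least
#' `min_alt_reads` *clean* observations -- far enough from both read ends and
#' on reads whose flanks within `neighborhood_window` bp match the reference
#' -- with at least one on each mapping strand. End-distance and flank
#' filters decide which observations count as clean support; quality gating
#' happens before any counting, so coverage means gated depth. Rejection is
#' a value carrying a machine-readable reason, not an error.
#'
#' @param col_obs Gated observations of one position (rows of a `pileup`
#'   `obs` table, single `pos`).
#' @param params [caller_params()].
#' @param mismatch_index Optional list mapping `read_id` to the positions at
#'   which that read mismatches the reference (from the whole pileup); if
#'   omitted the neighborhood filter cannot see other columns and passes.
#' @return List with `accepted` (logical); when accepted: `position`, `ref`,
#'   `alt`, `alt_reads`, `total_reads`, `allele_fraction`, `alt_fwd`,
#'   `alt_rev`; when rejected: `reason` (one of `no_variant`,
#'   `min_coverage`, `multiallelic`, `min_alt_reads`, `support_filtered`,
#'   `strand_requirement`).
#' @export
call_column <- function(col_obs, params = caller_params(),
                        mismatch_index = NULL) {
  pos <- col_obs$pos[1L]
  ref <- col_obs$ref[1L]
  reject <- function(reason)
    list(accepted = FALSE, position = pos, ref = ref, reason = reason)
  depth <- nrow(col_obs)
  if (depth < params$min_coverage) return(reject("min_coverage"))
  is_alt <- col_obs$base != ref
  if (!any(is_alt)) return(reject("no_variant"))
  alt_counts <- sort(table(col_obs$base[is_alt]), decreasing = TRUE)
  presence <- min(2L, max(1L, params$min_alt_reads))
  if (sum(alt_counts >= presence) >= 2L) return(reject("multiallelic"))
  alt <- names(alt_counts)[1L]
  sup <- col_obs[col_obs$base == alt, , drop = FALSE]
  raw_support <- nrow(sup)
  # clean support: far from read ends, reference-matching flanks
  end_ok <- is.na(sup$dist5) | is.na(sup$dist3) |
    (pmin(sup$dist5, sup$dist3) >= params$min_read_end_distance)
  sup <- sup[end_ok, , drop = FALSE]
  if (!is.null(mismatch_index) && nrow(sup) && params$neighborhood_window > 0L) {
    w <- params$neighborhood_window
    clean <- vapply(sup$read_id, function(id) {
      mm <- mismatch_index[[id]]
      if (is.null(mm)) return(TRUE)
      mm <- mm[mm != pos]
      !any(abs(mm - pos) <= w)
    }, logical(1))
    sup <- sup[clean, , drop = FALSE]
  }
  if (nrow(sup) < params$min_alt_reads)
    return(reject(if (raw_support < params$min_alt_reads) "min_alt_reads"
                  else "support_filtered"))
  n_fwd <- sum(sup$strand == "+", na.rm = TRUE)
  n_rev <- sum(sup$strand == "-", na.rm = TRUE)
  if (params$require_both_strands && (n_fwd == 0L || n_rev == 0L))
    return(reject("strand_requirement"))
  list(accepted = TRUE, position = pos, ref = ref, alt = alt,
       alt_reads = nrow(sup), total_reads = depth,
       allele_fraction = nrow(sup) / depth,
       alt_fwd = n_fwd, alt_rev = n_rev)
}

#' Call variants over a parsed pileup
#'
#' Applies the quality gates, then [call_column()] to every position with at
#' least one gated non-reference observation (the neighborhood filter sees
#' the full pileup through the read-mismatch index). Indels are excluded
#' from calling.
#'
#' @param pileup A [parse_pileup()] result.
#' @param params [caller_params()].
#' @return List with `calls` (data frame of accepted candidates) and
#'   `rejections` (data frame `position`, `reason`).
#' @export
call_variants <- function(pileup, params = caller_params()) {
  gated <- gate_observations(pileup$obs, params)
  mismatch_index <- read_mismatch_index(pileup$obs)
  res_calls <- list(); res_rej <- list()
  if (nrow(gated)) {
    alt_pos <- sort(unique(gated$pos[gated$base != gated$ref]))
    for (p in alt_pos) {
      col_obs <- gated[gated$pos == p, , drop = FALSE]
      res <- call_column(col_obs, params, mismatch_index)
      if (res$accepted) {
        res_calls[[length(res_calls) + 1L]] <-
          as.data.frame(res[c("position", "ref", "alt", "alt_reads",
                              "total_reads", "allele_fraction",
                              "alt_fwd", "alt_rev")])
      } else {
        res_rej[[length(res_rej) + 1L]] <-
          data.frame(position = res$position, reason = res$reason,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(
    calls = if (length(res_calls)) do.call(rbind, res_calls) else
      data.frame(position = integer(), ref = character(), alt = character(),
                 alt_reads = integer(), total_reads = integer(),
                 allele_fraction = numeric(), alt_fwd = integer(),
                 alt_rev = integer(), stringsAsFactors = FALSE),
    rejections = if (length(res_rej)) do.call(rbind, res_rej) else
      data.frame(position = integer(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Transition or transversion
#'
#' @param ref,alt Single bases.
#' @return `"Ts"` (purine<->purine or pyrimidine<->pyrimidine) or `"Tv"`.
#' @export
substitution_class <- function(ref, alt) {
  purines <- c("A", "G")
  ifelse((ref %in% purines) == (alt %in% purines), "Ts", "Tv")
}

#' Classify the protein-level effect of a codon change
#'
#' Pure function of the two codons and the genetic code: identical amino
#' acids are `synonymous`, a stop gained is `nonsense`, anything else
#' `non-synonymous`.
#'
#' @param ref_codon,alt_codon 3-letter codons on the coding strand.
#' @param code Genetic code.
#' @return List with `effect`, `ref_aa`, `alt_aa` (one-letter) and
#'   `aa_change` (e.g. `"Phe to Leu"`, `"Ser to STOP"`).
#' @export
classify_effect <- function(ref_codon, alt_codon, code = genetic_code()) {
  ref_aa <- unname(code[toupper(ref_codon)])
  alt_aa <- unname(code[toupper(alt_codon)])
  if (is.na(ref_aa) || is.na(alt_aa)) stop("invalid codon")
  effect <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else "non-synonymous"
  list(effect = effect, ref_aa = ref_aa, alt_aa = alt_aa,
       aa_change = paste(aa_three_letter(ref_aa), "to", aa_three_letter(alt_aa)))
}

#' Annotate calls with codon-level effects
#'
#' Maps each accepted call onto the annotation: codon index and offset via
#' [position_to_codon()], reference and alternative codons built on the
#' coding strand (for L-strand genes the alleles are complemented),
#' protein-level effect under the genetic code, and Ts/Tv class. A call in
#' two overlapping CDS yields one annotated row per gene; a call outside any
#' CDS is passed through with `gene = NA` and `effect = "non-coding"`.
#'
#' @param calls Data frame of accepted calls (from [call_variants()]).
#' @param genome A [mitogenome()] with annotations (or `annotations`
#'   supplied separately).
#' @param annotations Optional annotation table overriding
#'   `genome$annotations`.
#' @param code Genetic code.
#' @return Data frame: one row per call x overlapping gene, with columns
#'   `position, ref, alt, alt_reads, total_reads, allele_fraction, gene,
#'   substitution, class, codon_index, codon_change, aa_change, effect`.
#' @export
annotate_calls <- function(calls, genome, annotations = NULL,
                           code = genetic_code()) {
  if (is.null(annotations)) annotations <- genome$annotations
  if (is.null(annotations)) stop("no annotations available")
  out <- list()
  for (k in seq_len(nrow(calls))) {
    call <- calls[k, ]
    hits <- cds_at_position(annotations, call$position, genome$length)
    base_row <- data.frame(
      position = call$position, ref = call$ref, alt = call$alt,
      alt_reads = call$alt_reads, total_reads = call$total_reads,
      allele_fraction = call$allele_fraction,
      substitution = paste(call$ref, "to", call$alt),
      class = substitution_class(call$ref, call$alt),
      stringsAsFactors = FALSE)
    if (nrow(hits) == 0L) {
      row <- cbind(base_row, data.frame(
        gene = NA_character_, codon_index = NA_integer_,
        codon_change = NA_character_, aa_change = NA_character_,
        effect = "non-coding", stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- row
      next
    }
    for (h in seq_len(nrow(hits))) {
      g <- hits[h, ]
      loc <- position_to_codon(g, call$position, genome$length)
      gene_seq <- extract_gene_sequence(genome, g)
      cstart <- 3L * (loc$codon_index - 1L) + 1L
      ref_codon <- substr(gene_seq, cstart, cstart + 2L)
      if (nchar(ref_codon) < 3L)
        stop("codon ", loc$codon_index, " of ", g$name,
             " extends beyond the annotated CDS")
      strand_ref <- if (g$strand == "L") reverse_complement(call$ref) else call$ref
      strand_alt <- if (g$strand == "L") reverse_complement(call$alt) else call$alt
      if (substr(ref_codon, loc$offset, loc$offset) != strand_ref)
        stop("reference allele mismatch at position ", call$position,
             " in ", g$name)
      alt_codon <- ref_codon
      substr(alt_codon, loc$offset, loc$offset) <- strand_alt
      eff <- classify_effect(ref_codon, alt_codon, code)
      out[[length(out) + 1L]] <- cbind(base_row, data.frame(
        gene = g$name, codon_index = loc$codon_index,
        codon_change = paste(ref_codon, "to", alt_codon),
        aa_change = eff$aa_change, effect = eff$effect,
        stringsAsFactors = FALSE))
    }
  }
  if (!length(out))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), alt_reads = integer(),
                      total_reads = integer(), allele_fraction = numeric(),
                      substitution = character(), class = character(),
                      gene = character(), codon_index = integer(),
                      codon_change = character(), aa_change = character(),
                      effect = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-sample variant report
#'
#' Merges per-sample calls into one row per variant site with per-sample
#' `alt/total` support strings, flags for sites shared by several samples
#' and for sites where the reference individual itself carries the
#' alternative (reference heteroplasmy), and per-sample variant counts. The
#' reference sample's carriage is surfaced through the flag; its sites still
#' appear in its own support column.
#'
#' @param calls_by_sample Named list of annotated call data frames (one per
#'   sample; columns as from [annotate_calls()], or at least `position, ref,
#'   alt, alt_reads, total_reads`).
#' @param reference_sample Name of the reference individual (optional).
#' @return Data frame, one row per site (and gene, if annotated), with a
#'   `support_<sample>` column per sample, `n_samples`, `shared`,
#'   `in_reference`, and `min_allele_fraction` across carrying samples.
#'   Attributes: `sample_counts` (named variant counts per sample) and
#'   `sample_site_pairs` (total over non-reference samples).
#' @export
cross_sample_report <- function(calls_by_sample, reference_sample = NULL) {
  if (!length(calls_by_sample)) stop("no samples supplied")
  samples <- names(calls_by_sample)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("calls_by_sample must be a named list")
  all_calls <- do.call(rbind, lapply(samples, function(s) {
    df <- as.data.frame(calls_by_sample[[s]])
    if (!nrow(df)) return(NULL)
    df$sample <- s
    df
  }))
  if (is.null(all_calls) || !nrow(all_calls)) {
    out <- data.frame(position = integer())
    attr(out, "sample_counts") <- stats::setNames(rep(0L, length(samples)), samples)
    attr(out, "sample_site_pairs") <- 0L
    return(out)
  }
  ref_check <- tapply(all_calls$ref, all_calls$position,
                      function(x) length(unique(x)))
  if (any(ref_check > 1L))
    stop("inconsistent reference alleles across samples at position(s): ",
         paste(names(ref_check)[ref_check > 1L], collapse = ", "))
  keys <- sort(unique(all_calls$position))
  rows <- lapply(keys, function(p) {
    sub <- all_calls[all_calls$position == p, , drop = FALSE]
    row <- data.frame(position = p, ref = sub$ref[1L], alt = sub$alt[1L],
                      stringsAsFactors = FALSE)
    for (col in c("gene", "substitution", "class", "codon_index",
                  "codon_change", "aa_change", "effect"))
      if (col %in% names(sub)) row[[col]] <- sub[[col]][1L]
    for (s in samples) {
      ss <- sub[sub$sample == s, , drop = FALSE]
      row[[paste0("support_", s)]] <-
        if (nrow(ss)) paste0(ss$alt_reads[1L], "/", ss$total_reads[1L]) else ""
    }
    carrying <- unique(sub$sample)
    row$n_samples <- length(carrying)
    row$shared <- length(carrying) > 1L
    row$in_reference <- !is.null(reference_sample) &&
      reference_sample %in% carrying
    row$min_allele_fraction <- min(sub$alt_reads / sub$total_reads)
    row
  })
  out <- do.call(rbind, rows)
  counts <- stats::setNames(
    vapply(samples, function(s)
      length(unique(all_calls$position[all_calls$sample == s])), integer(1)),
    samples)
  attr(out, "sample_counts") <- counts
  nonref <- setdiff(samples, reference_sample)
  attr(out, "sample_site_pairs") <- sum(counts[nonref])
  out
}

#' Write accepted calls as a minimal VCF 4.2
#'
#' @param report Annotated calls or a cross-sample report row set with
#'   columns `position`, `ref`, `alt` (plus optional `allele_fraction`,
#'   `alt_fwd`, `alt_rev`).
#' @param path Output path.
#' @param contig Contig name for column 1.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(report, path, contig = "MT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitoasym",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
    "##INFO=<ID=SB,Number=2,Type=Integer,Description=\"Alt support fwd,rev\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(report)), function(i) {
    parts <- character(0)
    if ("allele_fraction" %in% names(report))
      parts <- c(parts, sprintf("AF=%.6g", report$allele_fraction[i]))
    if (all(c("alt_fwd", "alt_rev") %in% names(report)))
      parts <- c(parts, sprintf("SB=%d,%d", report$alt_fwd[i], report$alt_rev[i]))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  contig, report$position, report$ref, report$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}
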