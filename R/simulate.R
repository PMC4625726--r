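#' Specification of a synthetic circular mitogenome
#'
#' Defines the layout and composition of a generated genome. The default
#' layout is the full 38-feature organization of the A. charrua reference
#' annotation (13 CDS, 22 tRNA, 2 rRNA, control region at its published
#' coordinates), the default base composition is that mitogenome's measured
#' one, and the default control-region duplication is the published 180 bp
#' internal tandem repeat -- so a default synthetic genome has the same
#' coordinate arithmetic as the real one while its sequence is random.
#'
#' @param layout Annotation table giving the gene layout (coordinates,
#'   strands, start/stop codons). Defaults to [charrua_annotation()].
#' @param base_freqs Named target fractions for A, C, G, T (sum 1).
#' @param genome_length Total length; defaults to `max(layout$end)`.
#' @param cr_dup_length Length (bp) of the tandem duplication implanted
#'   inside the control region (0 to disable); must be shorter than half the
#'   control region.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(layout = charrua_annotation(),
                        base_freqs = c(A = 0.284, C = 0.222, G = 0.146, T = 0.348),
                        genome_length = NULL,
                        cr_dup_length = 180L,
                        seed = 1L) {
  base_freqs <- base_freqs[c("A", "C", "G", "T")]
  if (anyNA(base_freqs) || abs(sum(base_freqs) - 1) > 1e-6)
    stop("base_freqs must be named fractions for A,C,G,T summing to 1")
  layout <- validate_annotations(layout)
  if (is.null(genome_length)) genome_length <- max(layout$end)
  if (genome_length < max(layout$end))
    stop("genome_length shorter than the layout")
  cr <- layout[layout$feature_type == "CR", , drop = FALSE]
  if (cr_dup_length > 0L && nrow(cr)) {
    if (2L * cr_dup_length >= cr$end[1L] - cr$start[1L] + 1L)
      stop("duplication does not fit inside the control region")
  }
  structure(list(layout = layout, base_freqs = base_freqs,
                 genome_length = as.integer(genome_length),
                 cr_dup_length = as.integer(cr_dup_length),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

sample_bases <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# One random sense-strand codon from iid base draws, rejecting stops.
sample_nonstop_codons <- function(n, freqs, code) {
  stops <- names(code)[code == "*"]
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(sample_bases(n, freqs), sample_bases(n, freqs),
                   sample_bases(n, freqs))
    out <- c(out, cand[!cand %in% stops])
  }
  out[seq_len(n)]
}

#' Generate a synthetic circular mitogenome
#'
#' Builds a random sequence honouring the layout: every CDS begins with its
#' annotated start codon, is internally stop-free in its own reading frame
#' under the vertebrate mitochondrial code, and ends according to its stop
#' annotation (a complete stop codon, or the trailing `T`/`TA` of an
#' incomplete one); L-strand genes are written reverse-complemented into the
#' H strand. Intergenic, tRNA and rRNA sequence is drawn iid from the target
#' base composition, and the control region receives an internal tandem
#' duplication of the specified length. Overlapping genes are reconciled by
#' an iterative repair pass that removes any stop codon introduced into an
#' overlapped frame. Deterministic for a fixed seed.
#'
#' @param spec A [genome_spec()].
#' @param code Genetic code.
#' @return A [mitogenome()] with the layout attached; attribute `truth`
#'   records the spec and the duplication coordinates.
#' @export
generate_genome <- function(spec = genome_spec(), code = genetic_code()) {
  withr::with_seed(spec$seed, {
    L <- spec$genome_length
    genome <- sample_bases(L, spec$base_freqs)
    layout <- spec$layout
    dup <- NULL

    cr <- layout[layout$feature_type == "CR", , drop = FALSE]
    if (nrow(cr) && spec$cr_dup_length > 0L) {
      dlen <- spec$cr_dup_length
      lo <- cr$start[1L]; hi <- cr$end[1L]
      anchor <- sample(seq.int(lo, hi - 2L * dlen + 1L), 1L)
      genome[(anchor + dlen):(anchor + 2L * dlen - 1L)] <-
        genome[anchor:(anchor + dlen - 1L)]
      dup <- c(start = anchor, length = dlen)
    }

    write_feature <- function(genome, sense) {
      # `sense` is the 5'->3' coding-strand sequence; place on H strand
      if (g$strand == "L") sense <- reverse_complement(paste(sense, collapse = ""))
      chars <- strsplit(paste(sense, collapse = ""), "")[[1L]]
      idx <- ((seq.int(g$start, g$end) - 1L) %% L) + 1L
      genome[idx] <- chars
      genome
    }

    cds_rows <- which(layout$feature_type == "CDS")
    for (ri in cds_rows) {
      g <- layout[ri, ]
      len <- g$end - g$start + 1L
      stop_class <- classify_stop(g$stop_codon)
      tail_nt <- switch(stop_class,
                        complete = strsplit(toupper(g$stop_codon), "")[[1L]],
                        incomplete = strsplit(sub("-+$", "", toupper(g$stop_codon)), "")[[1L]],
                        none = character(0))
      body_codons <- (len - 3L - length(tail_nt)) %/% 3L
      if (3L + 3L * body_codons + length(tail_nt) != len)
        stop("CDS ", g$name, ": length ", len,
             " inconsistent with its stop class")
      sense <- c(strsplit(toupper(g$start_codon), "")[[1L]],
                 strsplit(paste(sample_nonstop_codons(body_codons,
                                                      spec$base_freqs, code),
                                collapse = ""), "")[[1L]],
                 tail_nt)
      genome <- write_feature(genome, sense)
    }

    # overlapping genes may have overwritten each other's start/stop codons;
    # re-impose them, verifying that overlapping requirements agree (true
    # mitochondrial overlaps, e.g. an upstream stop inside the downstream
    # gene, are compatible by construction of the layout)
    locked <- logical(L)
    for (ri in cds_rows) {
      g <- layout[ri, ]
      span <- ((seq.int(g$start, g$end) - 1L) %% L) + 1L
      stop_class <- classify_stop(g$stop_codon)
      start_sense <- strsplit(toupper(g$start_codon), "")[[1L]]
      tail_sense <- switch(stop_class,
                           complete = strsplit(toupper(g$stop_codon), "")[[1L]],
                           incomplete = strsplit(sub("-+$", "", toupper(g$stop_codon)), "")[[1L]],
                           none = character(0))
      sense_positions <- if (g$strand == "H") span else rev(span)
      req_pos <- c(sense_positions[seq_along(start_sense)],
                   if (length(tail_sense))
                     sense_positions[(length(span) - length(tail_sense) + 1L):length(span)])
      req_base <- c(start_sense, tail_sense)
      if (g$strand == "L")
        req_base <- chartr("ACGT", "TGCA", req_base)
      conflict <- locked[req_pos] & genome[req_pos] != req_base
      if (any(conflict))
        stop("incompatible overlapping codon requirements in ", g$name)
      genome[req_pos] <- req_base
      locked[req_pos] <- TRUE
    }
    # repair pass: replace any internal stop codon introduced into an
    # overlapped frame, touching only unlocked positions
    gtext <- function(genome) paste(genome, collapse = "")
    for (iter in 1:100) {
      fixed_any <- FALSE
      for (ri in cds_rows) {
        g <- layout[ri, ]
        seq_g <- extract_gene_sequence(mitogenome(gtext(genome), name = "tmp"), g)
        codons <- split_codons(substr(seq_g, 1L, nchar(seq_g) - nchar(seq_g) %% 3L))
        # the terminal codon of a complete-stop CDS is the stop itself
        n_check <- length(codons) -
          (classify_stop(g$stop_codon) == "complete")
        is_stop <- code[codons[seq_len(n_check)]] == "*"
        internal <- which(!is.na(is_stop) & is_stop)
        if (!length(internal)) next
        ci <- internal[1L]
        gene_positions <- (3L * (ci - 1L) + 1L):(3L * ci)
        span <- ((seq.int(g$start, g$end) - 1L) %% L) + 1L
        hpos <- if (g$strand == "H") span[gene_positions] else rev(span)[gene_positions]
        free <- which(!locked[hpos])
        if (!length(free))
          stop("cannot repair stop codon in ", g$name, ": all positions locked")
        done <- FALSE
        for (fp in free) {
          for (b in c("A", "C", "G", "T")) {
            old <- genome[hpos[fp]]
            if (b == old) next
            genome[hpos[fp]] <- b
            cand <- substr(extract_gene_sequence(
              mitogenome(gtext(genome), name = "tmp"), g),
              3L * (ci - 1L) + 1L, 3L * ci)
            if (code[cand] != "*") { done <- TRUE; break }
            genome[hpos[fp]] <- old
          }
          if (done) break
        }
        if (!done) stop("cannot repair stop codon in ", g$name)
        fixed_any <- TRUE
      }
      if (!fixed_any) break
      if (iter == 100L) stop("stop-codon repair did not converge")
    }

    gm <- mitogenome(gtext(genome), annotations = layout, name = "synthetic_mt")
    attr(gm, "truth") <- list(spec = spec, cr_duplication = dup)
    gm
  })
}

#' Specification of a synthetic single-end read experiment
#'
#' Emulates a deep single-end sequencing run over a circular genome at toy
#' scale: uniform read placement with wrap-around, 50/50 strand choice, a
#' flat per-base error rate multiplied by `end_bias_mult` over the last
#' `end_bias_len` bases of each read (errors pile up near the 3' end, the
#' behaviour the read-end filter is designed against), and a heteroplasmy
#' plan planting alternative bases at set per-read frequencies. Base
#' qualities are drawn from a high-quality profile for correct calls and a
#' low-quality profile for errors, reflecting the strong quality/error
#' correlation of Illumina data.
#'
#' @param coverage Mean fold coverage.
#' @param read_length Read length (bp); default 66, a short single-end cycle
#'   count.
#' @param error_rate Flat per-base error probability.
#' @param end_bias_len,end_bias_mult Length (bp) of the 3'-end window with
#'   elevated error rate, and its multiplier.
#' @param het_plan Data frame `position`, `alt`, `freq` of planted
#'   heteroplasmic sites (frequencies in (0,1)).
#' @param qual_correct,qual_error Mean and sd of the (normal, rounded,
#'   clipped to \[2, 41\]) base-quality distributions for correct and
#'   erroneous calls.
#' @param mapq Mapping quality assigned to every read.
#' @param seed RNG seed.
#' @return List of class `read_sim_spec`.
#' @export
read_sim_spec <- function(coverage = 100, read_length = 66L,
                          error_rate = 0.001,
                          end_bias_len = 5L, end_bias_mult = 8,
                          het_plan = NULL,
                          qual_correct = c(mean = 37, sd = 3),
                          qual_error = c(mean = 15, sd = 8),
                          mapq = 60L, seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(het_plan)) {
    het_plan <- as.data.frame(het_plan)
    stopifnot(all(c("position", "alt", "freq") %in% names(het_plan)))
    if (any(het_plan$freq <= 0 | het_plan$freq >= 1))
      stop("heteroplasmy frequencies must lie in (0, 1)")
  }
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, end_bias_len = as.integer(end_bias_len),
                 end_bias_mult = end_bias_mult, het_plan = het_plan,
                 qual_correct = qual_correct, qual_error = qual_error,
                 mapq = as.integer(mapq), seed = as.integer(seed)),
            class = "read_sim_spec")
}

rqual <- function(n, prof) {
  pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, prof[["mean"]],
                                                   prof[["sd"]])))))
}

#' Simulate a read pileup over a circular genome
#'
#' Places single-end reads uniformly on the circle (reads crossing the
#' origin are emitted as two segments, as a linear aligner would), plants
#' the heteroplasmy plan (each read covering a planted site carries the
#' alternative base independently with the site's frequency), injects
#' errors per the positional model, and serializes the result in the
#' extended pileup dialect that [parse_pileup()] reads (standard 6 columns
#' plus read-position and read-length columns). Ground truth is returned
#' alongside.
#'
#' @param genome A [mitogenome()] (or plain sequence string).
#' @param spec A [read_sim_spec()].
#' @return List of class `pileup_sim`: `lines` (pileup text), `truth` (per
#'   planted site: covering reads, alt reads planted, alt reads after
#'   errors), `errors` (injected error log: position, read, from, to, qual),
#'   `n_reads`.
#' @export
simulate_pileup <- function(genome, spec = read_sim_spec()) {
  if (inherits(genome, "mitogenome")) genome <- genome$sequence
  gchars <- strsplit(toupper(genome), "")[[1L]]
  L <- length(gchars)
  rl <- spec$read_length
  if (rl > L) stop("read length exceeds genome length")
  withr::with_seed(spec$seed, {
    n_reads <- max(1L, as.integer(round(spec$coverage * L / rl)))
    starts <- sample.int(L, n_reads, replace = TRUE)
    rstrand <- sample(c("+", "-"), n_reads, replace = TRUE)

    read <- rep(seq_len(n_reads), each = rl)
    offset <- rep(seq_len(rl) - 1L, times = n_reads)
    pos <- ((starts[read] + offset - 1L) %% L) + 1L
    # position within the read, counted from its 5' end
    read_pos <- ifelse(rstrand[read] == "+", offset + 1L, rl - offset)
    base <- gchars[pos]

    plan <- spec$het_plan
    alt_planted <- logical(length(pos))
    if (!is.null(plan) && nrow(plan)) {
      for (i in seq_len(nrow(plan))) {
        at <- which(pos == plan$position[i])
        carry <- at[stats::runif(length(at)) < plan$freq[i]]
        base[carry] <- plan$alt[i]
        alt_planted[carry] <- TRUE
      }
    }

    dist3 <- rl - read_pos
    err_rate <- ifelse(dist3 < spec$end_bias_len,
                       spec$error_rate * spec$end_bias_mult, spec$error_rate)
    is_err <- stats::runif(length(pos)) < err_rate
    if (any(is_err)) {
      from <- base[is_err]
      base[is_err] <- vapply(from, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    qual <- integer(length(pos))
    qual[!is_err] <- rqual(sum(!is_err), spec$qual_correct)
    qual[is_err] <- rqual(sum(is_err), spec$qual_error)

    # split wrapped reads into two segments for serialization
    wrapped <- pos < starts[read]
    seg_start <- ifelse(wrapped, 1L, starts[read])
    seg_id <- paste0(read, ifelse(wrapped, "b", "a"))
    first_off <- ifelse(wrapped, L - starts[read] + 1L, 0L)
    is_seg_first <- offset == first_off
    is_seg_last <- ifelse(wrapped | starts[read] + rl - 1L <= L,
                          offset == rl - 1L, offset == L - starts[read])

    ord <- order(pos, seg_start, read)
    df <- data.frame(pos = pos[ord], read = read[ord], base = base[ord],
                     strand = rstrand[read][ord], qual = qual[ord],
                     read_pos = read_pos[ord],
                     first = is_seg_first[ord], last = is_seg_last[ord])
    mapq_char <- intToUtf8(spec$mapq + 33L)
    by_pos <- split(seq_len(nrow(df)), df$pos)
    lines <- vapply(by_pos, function(ii) {
      sub <- df[ii, ]
      refb <- gchars[sub$pos[1L]]
      bchar <- ifelse(sub$base == refb,
                      ifelse(sub$strand == "+", ".", ","),
                      ifelse(sub$strand == "+", sub$base, tolower(sub$base)))
      bchar <- paste0(ifelse(sub$first, paste0("^", mapq_char), ""),
                      bchar,
                      ifelse(sub$last, "$", ""))
      paste(c("mt", sub$pos[1L], refb, nrow(sub),
              paste(bchar, collapse = ""),
              intToUtf8(sub$qual + 33L),
              paste(sub$read_pos, collapse = ","),
              paste(rep(rl, nrow(sub)), collapse = ",")),
            collapse = "\t")
    }, character(1))

    truth <- NULL
    if (!is.null(plan) && nrow(plan)) {
      truth <- plan
      truth$ref <- gchars[plan$position]
      truth$n_cov <- vapply(plan$position, function(p) sum(pos == p), integer(1))
      truth$n_alt_planted <- vapply(seq_len(nrow(plan)), function(i)
        sum(alt_planted[pos == plan$position[i]]), integer(1))
      truth$n_alt_final <- vapply(seq_len(nrow(plan)), function(i)
        sum(base[pos == plan$position[i]] == plan$alt[i]), integer(1))
    }
    errors <- data.frame(position = pos[is_err], read = read[is_err],
                         from = gchars[pos[is_err]], to = base[is_err],
                         qual = qual[is_err])
    structure(list(lines = unname(lines), truth = truth, errors = errors,
                   n_reads = n_reads),
              class = "pileup_sim")
  })
}

#' Sensitivity / false-positive recovery experiment
#'
#' For each (frequency, coverage) cell, repeatedly: generate a genome, plant
#' `n_sites` heteroplasmic sites, simulate and serialize a pileup, run the
#' caller, and score recovery against the truth. A planted site counts as
#' detected when an accepted call at its position reports its alternative
#' base; any other accepted call is a false positive.
#'
#' @param frequencies,coverages Numeric vectors defining the grid.
#' @param n_sites Planted sites per replicate.
#' @param replicates Replicates per cell.
#' @param genome_length Length of the toy genome.
#' @param params [caller_params()].
#' @param sim_args Extra arguments passed to [read_sim_spec()].
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Data frame with one row per cell x replicate (`frequency`,
#'   `coverage`, `replicate`, `sensitivity`, `false_positives`,
#'   `mean_af_error`) plus a `summary` attribute of per-cell means.
#' @export
recovery_experiment <- function(frequencies = 0.3, coverages = 100,
                                n_sites = 10L, replicates = 20L,
                                genome_length = 1200L,
                                params = caller_params(),
                                sim_args = list(), seed = 1L) {
  grid <- expand.grid(frequency = frequencies, coverage = coverages)
  if (!nrow(grid)) stop("empty grid")
  rows <- list()
  counter <- 0L
  for (gi in seq_len(nrow(grid))) {
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      rep_seed <- (seed + 7919L * counter) %% .Machine$integer.max
      gspec <- genome_spec(layout = toy_layout(genome_length),
                           genome_length = genome_length,
                           cr_dup_length = 0L, seed = rep_seed)
      gm <- generate_genome(gspec)
      gchars <- strsplit(gm$sequence, "")[[1L]]
      # planted sites: evenly spaced, away from the origin
      site_pos <- as.integer(round(seq(100L, genome_length - 100L,
                                       length.out = n_sites)))
      alts <- vapply(gchars[site_pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      plan <- data.frame(position = site_pos, alt = unname(alts),
                         freq = grid$frequency[gi])
      rspec <- do.call(read_sim_spec,
                       c(list(coverage = grid$coverage[gi], het_plan = plan,
                              seed = rep_seed + 1L), sim_args))
      sim <- simulate_pileup(gm, rspec)
      res <- call_variants(parse_pileup(sim$lines), params)
      calls <- res$calls
      detected <- vapply(seq_len(n_sites), function(i)
        any(calls$position == site_pos[i] & calls$alt == plan$alt[i]),
        logical(1))
      fp <- nrow(calls) - sum(calls$position %in% site_pos &
                                calls$alt == plan$alt[match(calls$position, site_pos)],
                              na.rm = TRUE)
      af_err <- if (any(detected)) {
        hit <- calls[calls$position %in% site_pos[detected], , drop = FALSE]
        mean(abs(hit$allele_fraction - grid$frequency[gi]))
      } else NA_real_
      rows[[counter]] <- data.frame(
        frequency = grid$frequency[gi], coverage = grid$coverage[gi],
        replicate = rep_i, sensitivity = mean(detected),
        false_positives = fp, mean_af_error = af_err)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(sensitivity, false_positives) ~ frequency + coverage,
                          data = out, FUN = mean)
  attr(out, "summary") <- agg
  out
}

#' Minimal toy gene layout for simulation experiments
#'
#' Two H-strand CDS, one L-strand CDS, one tRNA and a short control region
#' packed into `genome_length` bp -- enough structure to exercise strand
#' handling without the full 38-feature layout.
#'
#' @param genome_length Total length (>= 700 bp).
#' @return Annotation data frame.
#' @export
toy_layout <- function(genome_length = 1200L) {
  genome_length <- as.integer(genome_length)
  if (genome_length < 700L) stop("toy layout needs at least 700 bp")
  tab <- data.frame(
    name = c("CDS1", "tRNA-X", "CDS2", "CDS3", "CR"),
    start = c(10L, 320L, 400L, 581L, 642L),
    end = c(309L, 389L, 578L, 640L, min(942L, genome_length)),
    strand = c("H", "H", "H", "L", "H"),
    feature_type = c("CDS", "tRNA", "CDS", "CDS", "CR"),
    start_codon = c("ATG", NA, "ATG", "ATG", NA),
    stop_codon = c("TAA", NA, "TA-", "TAG", NA),
    stringsAsFactors = FALSE)
  tab
}
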