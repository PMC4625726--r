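params <- caller_params()

test_that("filter cascade rejects below-threshold columns with reason codes", {
  alt2 <- data.frame(base = "G", strand = c("+", "-"))
  # coverage 19, otherwise perfect
  col <- make_column(100L, "A", 17L, alt2)
  res <- call_column(col, params)
  expect_false(res$accepted)
  expect_identical(res$reason, "min_coverage")
  # two alt reads both on the forward strand
  col <- make_column(100L, "A", 30L, data.frame(base = "G", strand = c("+", "+")))
  res <- call_column(col, params)
  expect_identical(res$reason, "strand_requirement")
  # two different alt bases with two reads each
  col <- make_column(100L, "A", 30L,
                     data.frame(base = c("G", "G", "C", "C"),
                                strand = c("+", "-", "+", "-")))
  res <- call_column(col, params)
  expect_identical(res$reason, "multiallelic")
  # single alt read
  col <- make_column(100L, "A", 30L, data.frame(base = "G", strand = "+"))
  expect_identical(call_column(col, params)$reason, "min_alt_reads")
  # support near the read ends is filtered out
  col <- make_column(100L, "A", 30L,
                     data.frame(base = "G", strand = c("+", "-"),
                                dist5 = c(1L, 2L), dist3 = c(60L, 60L)))
  expect_identical(call_column(col, params)$reason, "support_filtered")
})

test_that("a clean heteroplasmic column is accepted with its allele fraction", {
  col <- make_column(15735L, "T", 49L,
                     data.frame(base = "C",
                                strand = rep(c("+", "-"), 22L)))
  res <- call_column(col, params)
  expect_true(res$accepted)
  expect_identical(res$alt, "C")
  expect_identical(res$alt_reads, 44L)
  expect_identical(res$total_reads, 93L)
  expect_equal(res$allele_fraction, 44 / 93)
})

test_that("substitutions classify as transitions or transversions", {
  expect_identical(substitution_class("A", "G"), "Ts")
  expect_identical(substitution_class("C", "T"), "Ts")
  expect_identical(substitution_class("C", "A"), "Tv")
  expect_identical(substitution_class("G", "T"), "Tv")
})

test_that("effect classification agrees with the translation oracle on all single-nucleotide changes", {
  code <- genetic_code()
  oracle <- Biostrings::getGeneticCode("2")
  bases <- c("A", "C", "G", "T")
  n_checked <- 0L
  for (codon in names(code)) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(codon, p, p))) {
        alt_codon <- codon
        substr(alt_codon, p, p) <- b
        got <- classify_effect(codon, alt_codon)
        want <- if (oracle[[codon]] == oracle[[alt_codon]]) "synonymous"
        else if (oracle[[alt_codon]] == "*") "nonsense"
        else "non-synonymous"
        expect_identical(got$effect, want,
                         info = paste(codon, "->", alt_codon))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_identical(n_checked, 64L * 9L)
})

test_that("calls annotate onto genes with strand-aware codons", {
  gm <- toy_genome(seed = 61L)
  ann <- gm$annotations
  # H-strand CDS: pick codon 5, offset 2 of CDS1 (start 10)
  pos_h <- 10L + 3L * 4L + 1L
  ref_h <- substr(gm$sequence, pos_h, pos_h)
  alt_h <- setdiff(c("A", "C", "G", "T"), ref_h)[1L]
  calls <- data.frame(position = pos_h, ref = ref_h, alt = alt_h,
                      alt_reads = 5L, total_reads = 50L,
                      allele_fraction = 0.1)
  out <- annotate_calls(calls, gm)
  expect_identical(out$gene, "CDS1")
  expect_identical(out$codon_index, 5L)
  gene_seq <- extract_gene_sequence(gm, ann[ann$name == "CDS1", ])
  ref_codon <- substr(gene_seq, 13L, 15L)
  alt_codon <- ref_codon
  substr(alt_codon, 2L, 2L) <- alt_h  # gene_pos 14 = codon 5, offset 2
  expect_identical(out$codon_change, paste(ref_codon, "to", alt_codon))
  # L-strand CDS: alleles must be complemented onto the coding strand
  g_l <- ann[ann$name == "CDS3", ]
  pos_l <- g_l$start + 10L
  ref_l <- substr(gm$sequence, pos_l, pos_l)
  alt_l <- setdiff(c("A", "C", "G", "T"), ref_l)[1L]
  out_l <- annotate_calls(data.frame(position = pos_l, ref = ref_l,
                                     alt = alt_l, alt_reads = 3L,
                                     total_reads = 40L,
                                     allele_fraction = 0.075), gm)
  expect_identical(out_l$gene, "CDS3")
  loc <- position_to_codon(g_l, pos_l)
  gseq <- extract_gene_sequence(gm, g_l)
  expect_identical(substr(strsplit(out_l$codon_change, " to ")[[1L]][1L],
                          loc$offset, loc$offset),
                   reverse_complement(ref_l))
  expect_identical(substr(gseq, 3L * (loc$codon_index - 1L) + loc$offset,
                          3L * (loc$codon_index - 1L) + loc$offset),
                   reverse_complement(ref_l))
  # effect agrees with classify_effect of the two reported codons
  cod <- strsplit(out_l$codon_change, " to ")[[1L]]
  expect_identical(out_l$effect, classify_effect(cod[1L], cod[2L])$effect)
  # non-coding position passes through
  out_nc <- annotate_calls(data.frame(position = 350L, ref = substr(gm$sequence, 350, 350),
                                      alt = "A", alt_reads = 2L, total_reads = 30L,
                                      allele_fraction = 0.07), gm)
  expect_identical(out_nc$effect, "non-coding")
  expect_true(is.na(out_nc$gene))
  # a position inside two overlapping genes yields two annotated rows
  overlap_ann <- mitoasym:::validate_annotations(data.frame(
    name = c("gA", "gB"), start = c(10L, 28L), end = c(30L, 48L),
    strand = "H", feature_type = "CDS", start_codon = "ATG",
    stop_codon = c("TAA", "TAA")))
  gm2 <- mitogenome(paste0(strrep("A", 9), "ATG", strrep("CAT", 4), "GCATAA",
                           strrep("CAT", 5), "TAA", strrep("A", 30)))
  gm2$annotations <- overlap_ann
  pos_o <- 29L
  ref_o <- substr(gm2$sequence, pos_o, pos_o)
  out_o <- annotate_calls(data.frame(position = pos_o, ref = ref_o, alt = "T",
                                     alt_reads = 2L, total_reads = 25L,
                                     allele_fraction = 0.08), gm2)
  expect_identical(sort(out_o$gene), c("gA", "gB"))
})

test_that("caller equals the brute-force criteria restatement on fuzzed pileups", {
  gm <- toy_genome(seed = 71L, genome_length = 900L)
  n_cols <- 0L
  for (rep_i in 1:4) {
    # noisy, low-coverage pileups so every filter gets exercised
    plan <- data.frame(position = c(120L, 430L, 640L),
                       alt = vapply(c(120L, 430L, 640L), function(p)
                         setdiff(c("A", "C", "G", "T"),
                                 substr(gm$sequence, p, p))[1L], character(1)),
                       freq = c(0.35, 0.12, 0.5))
    sim <- simulate_pileup(gm, read_sim_spec(
      coverage = 30, error_rate = 0.02, end_bias_mult = 4,
      qual_error = c(mean = 34, sd = 4),  # errors mostly survive the Q30 gate
      het_plan = plan, seed = 300L + rep_i))
    pu <- parse_pileup(sim$lines)
    p_var <- caller_params(min_coverage = sample(c(5L, 20L), 1L),
                           min_alt_reads = sample(2:3, 1L),
                           min_read_end_distance = sample(c(0L, 5L), 1L),
                           neighborhood_window = sample(c(0L, 5L), 1L))
    got <- call_variants(pu, p_var)$calls
    want <- oracle_calls(pu, p_var)
    expect_equal(got[order(got$position), c("position", "alt")],
                 want[order(want$position), c("position", "alt")],
                 ignore_attr = TRUE)
    n_cols <- n_cols + nrow(pu$sites)
  }
  expect_gt(n_cols, 1000L)  # fuzzed columns examined
})

test_that("raising any caller threshold never adds accepted calls", {
  gm <- toy_genome(seed = 81L, genome_length = 900L)
  plan <- data.frame(position = c(150L, 500L),
                     alt = vapply(c(150L, 500L), function(p)
                       setdiff(c("A", "C", "G", "T"),
                               substr(gm$sequence, p, p))[1L], character(1)),
                     freq = c(0.3, 0.08))
  sim <- simulate_pileup(gm, read_sim_spec(
    coverage = 40, error_rate = 0.015, qual_error = c(mean = 34, sd = 4),
    het_plan = plan, seed = 400L))
  pu <- parse_pileup(sim$lines)
  base <- caller_params(min_coverage = 10L, min_alt_reads = 2L,
                        min_read_end_distance = 2L, neighborhood_window = 2L)
  key <- function(calls) paste(calls$position, calls$alt)
  base_set <- key(call_variants(pu, base)$calls)
  bumps <- list(list(min_coverage = 25L), list(min_alt_reads = 4L),
                list(min_read_end_distance = 8L), list(neighborhood_window = 6L))
  for (b in bumps) {
    p2 <- do.call(caller_params, utils::modifyList(
      base[setdiff(names(base), "max_alt_alleles")], b))
    expect_true(all(key(call_variants(pu, p2)$calls) %in% base_set),
                info = names(b))
  }
})

test_that("cross-sample report merges sites, flags sharing and reference carriage", {
  sup <- sibling_variant_support()
  calls_by_sample <- lapply(split(sup, sup$sample), function(df)
    df[, c("position", "gene", "ref", "alt", "alt_reads", "total_reads")])
  rep_tab <- cross_sample_report(calls_by_sample, reference_sample = "AUS7")
  expect_identical(nrow(rep_tab), 10L)
  counts <- attr(rep_tab, "sample_counts")
  expect_identical(counts[["AUS4"]], 5L)
  expect_identical(counts[["AUS5"]], 7L)
  expect_identical(attr(rep_tab, "sample_site_pairs"), 12L)
  shared <- rep_tab$position[rep_tab$shared]
  expect_identical(sort(shared), c(6245L, 15735L))
  expect_identical(rep_tab$position[rep_tab$in_reference], 15735L)
  cytb <- rep_tab[rep_tab$position == 15735L, ]
  expect_equal(cytb$min_allele_fraction, 15 / 53)
  expect_identical(cytb$support_AUS4, "44/93")
  # empty input and inconsistent references
  empty <- cross_sample_report(list(s1 = calls_by_sample$AUS4[0, ]))
  expect_identical(nrow(empty), 0L)
  bad <- calls_by_sample
  bad$AUS5$ref[bad$AUS5$position == 15735] <- "G"
  expect_error(cross_sample_report(bad), "inconsistent reference")
})

test_that("accepted calls serialize to parseable VCF", {
  rep_tab <- data.frame(position = c(100L, 250L), ref = c("A", "T"),
                        alt = c("G", "C"), allele_fraction = c(0.3, 0.45),
                        alt_fwd = c(3L, 10L), alt_rev = c(2L, 9L))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rep_tab, tmp)
  lines <- readLines(tmp)
  expect_identical(sum(!startsWith(lines, "#")), 2L)
  body <- strsplit(lines[!startsWith(lines, "#")][1L], "\t")[[1L]]
  expect_identical(body[c(2, 4, 5)], c("100", "A", "G"))
  expect_match(body[8], "AF=0.3")
})
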