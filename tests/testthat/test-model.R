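test_that("vertebrate mitochondrial code matches the reference translation table", {
  code <- genetic_code(2L)
  expect_length(code, 64L)
  expect_identical(code[["ATA"]], "M")
  expect_identical(code[["TGA"]], "W")
  expect_identical(code[["AGA"]], "*")
  expect_identical(code[["AGG"]], "*")
  ref <- Biostrings::getGeneticCode("2")
  expect_identical(as.character(code[names(ref)]), as.character(ref))
  ref1 <- Biostrings::getGeneticCode("1")
  code1 <- genetic_code(1L)
  expect_identical(as.character(code1[names(ref1)]), as.character(ref1))
})

test_that("annotation table reader validates and sorts", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tstart\tend\tstrand\tfeature_type\tstart_codon\tstop_codon",
               "tRNA-Cys\t5343\t5399\tL\ttRNA\t\t",
               "ND1\t2854\t3828\tH\tCDS\tATG\tTAA"), tmp)
  tab <- read_annotation_table(tmp)
  expect_identical(tab$name, c("ND1", "tRNA-Cys"))  # sorted by start
  expect_identical(tab$end - tab$start + 1L, c(975L, 57L))

  # empty file -> empty collection
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tstart\tend\tstrand\tfeature_type\tstart_codon\tstop_codon", tmp2)
  expect_identical(nrow(read_annotation_table(tmp2)), 0L)

  bad <- data.frame(name = c("A", "A"), start = c(1, 60), end = c(55, 120),
                    strand = "H", feature_type = "rRNA")
  expect_error(mitoasym:::validate_annotations(bad), "duplicate")
  bad2 <- data.frame(name = "x", start = 10, end = 5, strand = "H",
                     feature_type = "rRNA")
  expect_error(mitoasym:::validate_annotations(bad2), "end < start")
  bad3 <- data.frame(name = "x", start = 1, end = 70, strand = "W",
                     feature_type = "tRNA")
  expect_error(mitoasym:::validate_annotations(bad3), "strand")
})

test_that("gene extraction honours strand and the circular origin", {
  gm <- mitogenome("ACGTACGT")
  expect_identical(extract_gene_sequence(gm, list(start = 2, end = 4, strand = "H")), "CGT")
  expect_identical(extract_gene_sequence(gm, list(start = 2, end = 4, strand = "L")), "ACG")

  gm10 <- mitogenome("ACGTACGTAC")
  expect_identical(extract_gene_sequence(gm10, list(start = 9, end = 12, strand = "H")),
                   oracle_extract("ACGTACGTAC", 9, 12))

  # fuzzed wrap-around extraction against the rotation oracle
  set.seed(3)
  for (i in 1:25) {
    s <- random_dna(sample(20:60, 1))
    L <- nchar(s)
    st <- sample(L, 1)
    en <- st + sample(0:(L - 1), 1)
    strand <- sample(c("H", "L"), 1)
    expect_identical(
      extract_gene_sequence(mitogenome(s), list(start = st, end = en, strand = strand)),
      oracle_extract(s, st, en, strand))
  }
  expect_error(extract_gene_sequence(gm, list(start = 20, end = 22, strand = "H")),
               "beyond")
})

test_that("H and L extraction of the same interval are reverse complements", {
  set.seed(4)
  for (i in 1:10) {
    s <- random_dna(50)
    st <- sample(40, 1); en <- st + sample(0:9, 1)
    h <- extract_gene_sequence(mitogenome(s), list(start = st, end = en, strand = "H"))
    l <- extract_gene_sequence(mitogenome(s), list(start = st, end = en, strand = "L"))
    expect_identical(reverse_complement(l), h)
  }
})

test_that("translation handles complete and incomplete stops", {
  expect_identical(as.character(translate_cds("ATGTTTTAA")), "MF")
  expect_identical(as.character(translate_cds("ATA")), "M")
  expect_identical(as.character(translate_cds("ATGNNNAAA")), "MXK")
  expect_error(translate_cds("AT"), "at least 3")
  expect_error(translate_cds("ATGT"), "multiple of 3")
  # trailing T of an incomplete stop is ignored
  expect_identical(as.character(translate_cds("ATGTTTT", incomplete_stop = TRUE)), "MF")
  # internal stops are reported, not dropped
  pep <- translate_cds("ATGAGATTTTAA")
  expect_identical(as.character(pep), "M*F")
  expect_identical(attr(pep, "internal_stops"), 2L)
})

test_that("translated length follows the stop-class rule on every annotated CDS", {
  gm <- generate_genome(genome_spec(seed = 5L))
  fl <- feature_lengths(gm$annotations)
  for (i in which(fl$feature_type == "CDS")) {
    g <- fl[i, ]
    pep <- translate_cds(extract_gene_sequence(gm, g), incomplete_stop = TRUE)
    expect_identical(nchar(pep), as.integer(g$aa_length),
                     info = paste("aa length of", g$name))
    expect_length(attr(pep, "internal_stops"), 0L)
  }
})

test_that("position_to_codon maps coordinates to codon index and offset", {
  ann <- charrua_annotation()
  nd2 <- ann[ann$name == "ND2", ]
  expect_identical(position_to_codon(nd2, 4105),
                   list(codon_index = 22L, offset = 2L))
  expect_identical(position_to_codon(ann[ann$name == "COI", ], 6245),
                   list(codon_index = 260L, offset = 3L))
  expect_identical(position_to_codon(ann[ann$name == "Cytb", ], 15735),
                   list(codon_index = 368L, offset = 1L))
  expect_identical(position_to_codon(nd2, nd2$start),
                   list(codon_index = 1L, offset = 1L))
  expect_error(position_to_codon(nd2, 4040), "outside")
  expect_error(position_to_codon(ann[ann$name == "tRNA-Phe", ], 10), "CDS")
})

test_that("codon round trip: codon_index/offset reproduce the genome base", {
  gm <- toy_genome()
  gchars <- strsplit(gm$sequence, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds <- gm$annotations[gm$annotations$feature_type == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    g <- cds[i, ]
    gene_seq <- extract_gene_sequence(gm, g)
    for (pos in seq(g$start, g$end, by = 7L)) {
      loc <- position_to_codon(g, pos)
      gene_pos <- 3L * (loc$codon_index - 1L) + loc$offset
      base_in_gene <- substr(gene_seq, gene_pos, gene_pos)
      expected <- if (g$strand == "H") gchars[pos] else comp[[gchars[pos]]]
      expect_identical(base_in_gene, expected,
                       info = paste(g$name, pos))
    }
  }
})

test_that("GenBank reader maps features onto the annotation model", {
  gb <- c(
    "LOCUS       TESTMT                 120 bp    DNA     circular VRT",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..45",
    "                     /gene=\"ND1\"",
    "     tRNA            complement(50..119)",
    "                     /product=\"tRNA-Cys\"",
    "     D-loop          46..49",
    "ORIGIN",
    paste0("        1 ", paste(substring(random_dna(60, seed = 9),
                                         seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    paste0("       61 ", paste(substring(random_dna(60, seed = 10),
                                         seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    "//")
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tmp)
  gm <- read_genbank(tmp)
  expect_s3_class(gm, "mitogenome")
  expect_identical(gm$length, 120L)
  ann <- gm$annotations
  expect_identical(ann$name, c("ND1", "D-loop_46", "tRNA-Cys"))
  expect_identical(ann$feature_type, c("CDS", "CR", "tRNA"))
  expect_identical(ann$strand, c("H", "H", "L"))
  expect_identical(ann$start_codon[1L], substr(gm$sequence, 10, 12))
})

test_that("FASTA round trip preserves the sequence", {
  gm <- toy_genome()
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(gm, tmp)
  back <- read_genome_fasta(tmp)
  expect_identical(back$sequence, gm$sequence)
})
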