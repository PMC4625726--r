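#' Pipeline run configuration
#'
#' Collects and validates everything a full run needs: input paths, caller
#' parameters, composition options, output directory and seed. A config is
#' fully serializable (echoed into the run manifest as YAML-compatible
#' lists), so any run can be reproduced from its manifest.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param annotation_tsv Path to the annotation TSV.
#' @param pileups Named character vector of per-sample pileup paths
#'   (optional; empty disables variant calling).
#' @param reference_sample Name of the reference individual among `pileups`.
#' @param params [caller_params()].
#' @param genetic_code_id Genetic code identifier (default 2).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest and used for any stochastic
#'   stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome_fasta, annotation_tsv, pileups = character(0),
                       reference_sample = NULL, params = caller_params(),
                       genetic_code_id = 2L, out_dir = "mitoasym_out",
                       seed = 1L) {
  for (p in c(genome_fasta, annotation_tsv, unname(pileups)))
    if (!file.exists(p)) stop("input not found: ", p)
  if (length(pileups) && is.null(names(pileups)))
    names(pileups) <- paste0("sample", seq_along(pileups))
  structure(list(genome_fasta = genome_fasta, annotation_tsv = annotation_tsv,
                 pileups = pileups, reference_sample = reference_sample,
                 params = params, genetic_code_id = as.integer(genetic_code_id),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_hash <- function(config) {
  plain <- strip_classes(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: annotation summary, whole-genome composition and
#' H-strand CDS codon-position profile, codon usage, per-gene correspondence
#' analysis, and (when pileups are supplied) variant calling with codon-level
#' annotation and a cross-sample report. Writes TSV/JSON artifacts plus a
#' manifest echoing the package version, configuration and its hash; the
#' outputs carry no timestamps, so identical config and seed give
#' byte-identical reports.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  code <- genetic_code(config$genetic_code_id)
  annotations <- read_annotation_table(config$annotation_tsv)
  genome <- read_genome_fasta(config$genome_fasta, annotations = annotations)

  summ <- annotation_summary(annotations, genome$length)
  paths$annotation_tsv <- file.path(config$out_dir, "annotation_summary.tsv")
  utils::write.table(summ$features, paths$annotation_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  paths$annotation_json <- file.path(config$out_dir, "annotation_summary.json")
  jsonlite::write_json(summ$genome, paths$annotation_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  h_cds <- annotations[annotations$feature_type == "CDS" &
                         annotations$strand == "H", , drop = FALSE]
  cds_seqs <- stats::setNames(
    lapply(seq_len(nrow(h_cds)), function(i)
      extract_gene_sequence(genome, h_cds[i, ])), h_cds$name)
  comp <- composition(genome$sequence)
  prof <- codon_position_profile(unlist(cds_seqs), code = code)
  paths$composition_json <- file.path(config$out_dir, "composition.json")
  jsonlite::write_json(
    list(whole_genome = unclass(comp)[c("n", "fA", "fC", "fG", "fT", "gc",
                                        "gc_skew", "at_skew")],
         h_strand_cds = list(gc_percent = as.list(prof$gc_percent),
                             coding_gc = prof$coding_gc,
                             n_codons = prof$n_codons)),
    paths$composition_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  usage <- codon_usage(unlist(cds_seqs), code = code)
  paths$codon_usage_tsv <- file.path(config$out_dir, "codon_usage.tsv")
  utils::write.table(
    data.frame(codon = names(usage), aa = unname(code[names(usage)]),
               count = as.integer(usage), rscu = unname(rscu(usage))),
    paths$codon_usage_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(cds_seqs) >= 3L) {
    ca_tab <- composition_ca_table(
      stats::setNames(lapply(cds_seqs, identity), names(cds_seqs)), code = code)
    fit <- correspondence_analysis(ca_tab)
    paths$ca_tsv <- file.path(config$out_dir, "ca_coordinates.tsv")
    coords <- rbind(
      data.frame(label = rownames(fit$row_coords), set = "gene",
                 fit$row_coords, check.names = FALSE),
      data.frame(label = rownames(fit$col_coords), set = "category",
                 fit$col_coords, check.names = FALSE))
    utils::write.table(coords, paths$ca_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if (length(config$pileups)) {
    calls_by_sample <- lapply(config$pileups, function(pp) {
      res <- call_variants(parse_pileup(pp), config$params)
      annotate_calls(res$calls, genome, code = code)
    })
    report <- cross_sample_report(calls_by_sample,
                                  reference_sample = config$reference_sample)
    paths$variants_tsv <- file.path(config$out_dir, "variants.tsv")
    utils::write.table(report, paths$variants_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    paths$variants_vcf <- file.path(config$out_dir, "variants.vcf")
    if (nrow(report)) write_vcf(report, paths$variants_vcf, contig = genome$name)
    else writeLines("##fileformat=VCFv4.2", paths$variants_vcf)
  }

  manifest <- list(
    package = "mitoasym",
    version = as.character(utils::packageVersion("mitoasym")),
    seed = config$seed,
    config = strip_classes(config),
    config_hash = config_hash(config),
    artifacts = lapply(paths, basename))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
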