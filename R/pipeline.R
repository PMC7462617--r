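#' Pipeline configuration
#'
#' Collects every input path and numeric threshold of the end-to-end
#' analysis. Defaults are the study constants: differential accessibility
#' at FDR 0.10, differential expression calls at adjusted p < 0.05 and at
#' |log2fc| >= 1 & FDR <= 0.01, coupling at FDR 0.1 in both assays,
#' 150 kb annotation window, 400 bp summit windows (flank 200), 20,000
#' random background sequences of 400 bp, order-3 combinations within
#' 500 bp, detection at the 95th percentile of 5 kb intergenic windows.
#'
#' @param dataset_dir directory holding the dataset (layout of
#'   [write_dataset()]); individual paths can be overridden.
#' @param ... overrides for any config entry.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset_dir = NULL, ...) {
  cfg <- list(
    dataset_dir = dataset_dir,
    genome = NULL, genes = NULL, motifs = NULL,
    gene_counts = NULL, peak_counts = NULL, intergenic_counts = NULL,
    peak_loci = NULL, narrowpeaks_A = NULL, narrowpeaks_B = NULL,
    da_fdr = 0.10, da_lfc_filter = 0,
    de_adj_p = 0.05, de_volcano_lfc = 1, de_volcano_fdr = 0.01,
    coupling_fdr = 0.1,
    annotation_window = 150000L, tss_margin = 1000L,
    summit_flank = 200L,
    background_n = 20000L, background_len = 400L,
    combination_order = 3L, combination_span = 500L,
    scan_threshold = 0.8,
    detection_percentile = 95, intergenic_window = 5000L,
    min_support = 2L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown pipeline config entries: %s",
              paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!is.null(cfg$dataset_dir)) {
    d <- cfg$dataset_dir
    fill <- function(cur, file) cur %||% file.path(d, file)
    cfg$genome <- fill(cfg$genome, "genome.fa")
    cfg$genes <- fill(cfg$genes, "genes.tsv")
    cfg$motifs <- fill(cfg$motifs, "motifs.pfm")
    cfg$gene_counts <- fill(cfg$gene_counts, "gene_counts.tsv")
    cfg$peak_counts <- fill(cfg$peak_counts, "peak_counts.tsv")
    cfg$intergenic_counts <- fill(cfg$intergenic_counts, "intergenic_counts.tsv")
    cfg$peak_loci <- fill(cfg$peak_loci, "peak_loci.tsv")
    if (is.null(cfg$narrowpeaks_A)) {
      cfg$narrowpeaks_A <- sort(list.files(d, "^A_rep.*\\.narrowPeak$",
                                           full.names = TRUE))
    }
    if (is.null(cfg$narrowpeaks_B)) {
      cfg$narrowpeaks_B <- sort(list.files(d, "^B_rep.*\\.narrowPeak$",
                                           full.names = TRUE))
    }
  }
  assert_that(cfg$da_fdr > 0 && cfg$da_fdr < 1 && cfg$coupling_fdr > 0 &&
                cfg$coupling_fdr < 1 && cfg$de_adj_p > 0 && cfg$de_adj_p < 1,
              "FDR/p thresholds must lie in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `pipeline_config` entries.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full two-population analysis pipeline
#'
#' Stages, in dependency order: expression (size factors, null filter,
#' detection threshold, expressed partition, differential expression) and
#' accessibility (consensus merging, classification, counts over pooled
#' peaks, differential accessibility, annotation, TSS
#' over-representation) run independently; coupling joins them; the motif
#' stage scans A-exclusive summit windows against random genomic
#' background for single-motif and order-3 combination enrichment.
#' Deterministic given `config$seed`.
#'
#' @param config [pipeline_config()].
#' @param out_dir optional output directory for stage TSV/JSON files.
#' @return List with every stage result and a `summary` list (the machine
#'   readable report).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  for (f in c("genome", "genes", "motifs", "gene_counts", "peak_counts",
              "intergenic_counts", "peak_loci")) {
    assert_that(!is.null(config[[f]]) && file.exists(config[[f]]),
                "input file for '%s' not found: %s", f,
                config[[f]] %||% "<unset>")
  }
  assert_that(length(config$narrowpeaks_A) > 0 && length(config$narrowpeaks_B) > 0,
              "no replicate narrowPeak files configured")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pipeline_log("reading inputs")
  genome <- read_genome(config$genome)
  genes <- read_gene_table(config$genes)
  pwms <- read_pfm(config$motifs)
  gene_counts <- read_count_table(config$gene_counts)
  peak_counts_raw <- read_count_table(config$peak_counts)
  intergenic <- read_count_table(config$intergenic_counts)
  loci <- read.delim(config$peak_loci, stringsAsFactors = FALSE)
  reps_A <- lapply(config$narrowpeaks_A, read_narrowpeak)
  reps_B <- lapply(config$narrowpeaks_B, read_narrowpeak)

  pipeline_log("expression stage")
  gene_counts <- filter_null_expression(gene_counts)
  sf_rna <- size_factors_median_of_ratios(gene_counts)
  thr <- detection_threshold(intergenic, sf_rna, config$detection_percentile)
  part <- partition_expressed(gene_counts, sf_rna, thr)
  de <- differential_expression(gene_counts, sf_rna,
                                alpha_adj_p = config$de_adj_p,
                                volcano_lfc = config$de_volcano_lfc,
                                volcano_fdr = config$de_volcano_fdr)

  pipeline_log("accessibility stage")
  cons_A <- merge_replicate_peaks(reps_A, config$min_support, "A")
  cons_B <- merge_replicate_peaks(reps_B, config$min_support, "B")
  classification <- classify_peaks(cons_A, cons_B)
  pooled <- classification$peaks
  peak_counts <- count_reads_in_peaks(pooled, counts = peak_counts_raw,
                                      loci = loci)
  sf_atac <- size_factors_median_of_ratios(peak_counts)
  da <- differential_accessibility(peak_counts, sf_atac,
                                   fdr_threshold = config$da_fdr,
                                   lfc_filter = config$da_lfc_filter)
  annotations <- annotate_peaks(pooled, genes, config$annotation_window,
                                config$tss_margin)
  annA <- annotations[classification$class == "exclusive_A", , drop = FALSE]
  annB <- annotations[classification$class == "exclusive_B", , drop = FALSE]
  tss_test <- if (nrow(annA) > 0 && nrow(annB) > 0)
    tss_overrepresentation(annA, annB) else NULL

  pipeline_log("coupling stage")
  coupling <- couple(annotations, da, de, config$coupling_fdr)

  pipeline_log("motif stage")
  excl_A_peaks <- pooled[classification$class == "exclusive_A", , drop = FALSE]
  motif <- NULL
  if (nrow(excl_A_peaks) >= 1) {
    summit_seqs <- extract_summit_sequences(excl_A_peaks, genome,
                                            config$summit_flank)
    background <- sample_background(genome, config$background_n,
                                    config$background_len,
                                    seed = child_seed(config$seed, "background"))
    motif <- list(
      summit_seqs = summit_seqs, background_n = length(background),
      single = single_motif_enrichment(summit_seqs, background, pwms,
                                       config$scan_threshold),
      combinations = combination_enrichment(summit_seqs, background, pwms,
                                            config$combination_order,
                                            config$combination_span,
                                            config$scan_threshold))
  }

  summary <- list(
    genes = list(n_tested = nrow(gene_counts$counts),
                 expressed_shared = length(part$shared),
                 expressed_specific_A = length(part$specific_A),
                 expressed_specific_B = length(part$specific_B),
                 detection_threshold = thr$value,
                 de_adj_p = sum(de$sig_adj_p),
                 de_volcano = sum(de$sig_volcano)),
    peaks = list(pooled = nrow(pooled),
                 counts = as.list(classification$counts),
                 fractions = as.list(classification$fractions),
                 da_significant = sum(da$significant),
                 tss_overrepresentation_p = if (is.null(tss_test)) NA
                                            else tss_test$p),
    coupling = as.list(coupling_summary(coupling)),
    top_combinations = if (is.null(motif)) NULL else
      utils::head(motif$combinations[, c(paste0("motif_",
                                                seq_len(config$combination_order)),
                                         "k_peak", "k_bg", "p", "fdr")], 5),
    provenance = list(seed = config$seed,
                      thresholds = config[c("da_fdr", "de_adj_p",
                                            "coupling_fdr",
                                            "detection_percentile")]))
  audit_summary(summary, part, classification, de, da, coupling)

  result <- list(config = config, size_factors = list(rna = sf_rna, atac = sf_atac),
                 threshold = thr, partition = part, de = de,
                 consensus = list(A = cons_A, B = cons_B),
                 classification = classification, peak_counts = peak_counts,
                 da = da, annotations = annotations, tss_test = tss_test,
                 coupling = coupling, motif = motif, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# internal consistency audit: report counts must equal recomputation
audit_summary <- function(summary, part, classification, de, da, coupling) {
  stopifnot(
    summary$genes$expressed_shared == length(intersect(part$expressed_A,
                                                       part$expressed_B)),
    sum(unlist(summary$peaks$counts)) == summary$peaks$pooled,
    summary$genes$de_adj_p == sum(de$sig_adj_p),
    summary$peaks$da_significant == sum(da$significant),
    sum(unlist(summary$coupling)) == nrow(coupling))
  invisible(TRUE)
}

write_pipeline_outputs <- function(result, out_dir) {
  write_narrowpeak(result$consensus$A,
                   file.path(out_dir, "consensus_A.narrowPeak"))
  write_narrowpeak(result$consensus$B,
                   file.path(out_dir, "consensus_B.narrowPeak"))
  write_narrowpeak(result$classification$peaks,
                   file.path(out_dir, "consensus_pooled.narrowPeak"))
  write.table(data.frame(peak_id = result$classification$peaks$name,
                         class = result$classification$class),
              file.path(out_dir, "peak_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_differential(result$da, file.path(out_dir, "da_results.tsv"))
  write_differential(result$de, file.path(out_dir, "de_results.tsv"))
  write.table(result$annotations, file.path(out_dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$da[, c("feature_id", "M", "A", "fdr")],
              file.path(out_dir, "ma_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  part <- result$partition
  pt <- data.frame(
    gene_id = c(part$shared, part$specific_A, part$specific_B),
    class = rep(c("shared", "specific_A", "specific_B"),
                c(length(part$shared), length(part$specific_A),
                  length(part$specific_B))))
  write.table(pt, file.path(out_dir, "partition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(value = result$threshold$value,
                            per_sample = as.list(result$threshold$per_sample),
                            percentile = result$threshold$percentile,
                            n_windows = result$threshold$n_windows),
                       file.path(out_dir, "threshold.json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(result$coupling, file.path(out_dir, "coupling.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(coupling_summary(result$coupling)),
                       file.path(out_dir, "coupling_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$motif)) {
    write_fasta(result$motif$summit_seqs, file.path(out_dir, "summit_seqs.fa"))
    write.table(result$motif$single,
                file.path(out_dir, "single_motif_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$motif$combinations,
                file.path(out_dir, "combination_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
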