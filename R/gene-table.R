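#' Read a flat gene table
#'
#' The gene model used throughout the package is minimal: one row per gene
#' with tab-separated columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open). The transcription start site is derived from the
#' strand: `start` for `+`, `end - 1` for `-`.
#'
#' @param path TSV file with a header row.
#' @return Data frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_table <- function(path) {
  assert_that(file.exists(path), "gene table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  assert_that(all(need %in% names(df)), "gene table: missing columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "))
  gene_table(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

#' Construct and validate a gene table
#'
#' @param gene_id,chrom,start,end,strand gene record fields.
#' @return Validated gene table data frame with a `tss` column.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  dup <- duplicated(df$gene_id)
  assert_that(!any(dup), "gene table: duplicated gene_id: %s", df$gene_id[dup][1])
  bad <- which(df$start >= df$end)
  assert_that(length(bad) == 0, "gene table: start >= end for gene %s",
              df$gene_id[bad[1]])
  assert_that(all(df$strand %in% c("+", "-")),
              "gene table: strand must be '+' or '-'")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Write a gene table to TSV
#' @param genes gene table data frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal GTF importer
#'
#' Extracts gene records (feature type `gene`) from a GTF file; only
#' gene_id, coordinates and strand are consumed. GTF is 1-based closed and
#' is converted to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return Gene table data frame (see [gene_table()]).
#' @export
read_gtf_genes <- function(path) {
  assert_that(file.exists(path), "GTF not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))
  f <- f[keep]
  assert_that(length(f) > 0, "GTF contains no gene records: %s", path)
  ids <- vapply(f, function(x) {
    m <- regmatches(x[9], regexec('gene_id[ =]+"?([^";]+)"?', x[9]))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }, character(1))
  assert_that(!anyNA(ids), "GTF gene record without gene_id attribute")
  gene_table(gene_id = ids,
             chrom = vapply(f, `[`, character(1), 1),
             start = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
             end = as.integer(vapply(f, `[`, character(1), 5)),
             strand = vapply(f, `[`, character(1), 7))
}
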