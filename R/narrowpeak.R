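#' narrowPeak data model
#'
#' Peaks are kept as plain data frames in BED narrowPeak (BED6+4) column
#' order with 0-based half-open coordinates: `chrom`, `start`, `end`,
#' `name`, `score`, `strand`, `signal`, `neglog10_p`, `neglog10_q`,
#' `summit_offset`. The summit offset is relative to `start`; -1 means the
#' summit is unknown, in which case the interval midpoint (floor) is used
#' wherever an absolute summit is required.
#'
#' @param chrom,start,end,name,score,strand,signal,neglog10_p,neglog10_q,summit_offset
#'   vectors of equal length (scalars are recycled).
#' @return A validated narrowPeak data frame.
#' @export
narrowpeak <- function(chrom, start, end, name = NULL,
                       score = 0L, strand = ".", signal = 0,
                       neglog10_p = -1, neglog10_q = -1, summit_offset = -1L) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0 || length(chrom) == 0) n <- 0L
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.integer(score), n),
                   strand = rep_len(as.character(strand), n),
                   signal = rep_len(as.numeric(signal), n),
                   neglog10_p = rep_len(as.numeric(neglog10_p), n),
                   neglog10_q = rep_len(as.numeric(neglog10_q), n),
                   summit_offset = rep_len(as.integer(summit_offset), n),
                   stringsAsFactors = FALSE)
  validate_narrowpeak(df)
  df
}

validate_narrowpeak <- function(df, what = "narrowPeak") {
  need <- c("chrom", "start", "end", "name", "score", "strand", "signal",
            "neglog10_p", "neglog10_q", "summit_offset")
  assert_that(all(need %in% names(df)), "%s: missing columns: %s", what,
              paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  assert_that(all(nzchar(df$chrom)), "%s: empty chrom name", what)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  assert_that(length(bad) == 0, "%s: invalid interval at row %d (start=%s end=%s)",
              what, bad[1], df$start[bad[1]], df$end[bad[1]])
  assert_that(all(df$strand %in% c("+", "-", ".")), "%s: invalid strand", what)
  bad <- which(!(df$summit_offset == -1L |
                 (df$summit_offset >= 0L & df$summit_offset < df$end - df$start)))
  assert_that(length(bad) == 0,
              "%s: summit_offset out of range at row %d (offset=%d width=%d)",
              what, bad[1], df$summit_offset[bad[1]],
              df$end[bad[1]] - df$start[bad[1]])
  invisible(df)
}

#' Absolute summit position of each peak
#'
#' Peaks without a recorded summit (`summit_offset == -1`) use the interval
#' midpoint, floored, as their summit.
#'
#' @param peaks narrowPeak data frame.
#' @return Integer vector of 0-based summit positions.
#' @export
peak_summit <- function(peaks) {
  off <- ifelse(peaks$summit_offset >= 0L, peaks$summit_offset,
                (peaks$end - peaks$start) %/% 2L)
  as.integer(peaks$start + off)
}

#' Read a narrowPeak (BED6+4) file
#'
#' @param path file path.
#' @return narrowPeak data frame sorted by (chrom, start).
#' @export
read_narrowpeak <- function(path) {
  assert_that(file.exists(path), "narrowPeak file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(narrowpeak(character(), integer(), integer())[0, ])
  }
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  bad <- which(nf != 10)
  assert_that(length(bad) == 0, "narrowPeak parse error at line %d: %d fields (10 expected)",
              bad[1], nf[bad[1]])
  m <- matrix(unlist(fields), ncol = 10, byrow = TRUE)
  num <- suppressWarnings(apply(m[, c(2, 3, 5, 7, 8, 9, 10), drop = FALSE], 2, as.numeric))
  if (length(lines) == 1) num <- matrix(num, nrow = 1)
  badnum <- which(apply(num, 1, function(r) any(is.na(r))))
  assert_that(length(badnum) == 0, "narrowPeak parse error at line %d: non-numeric field",
              badnum[1])
  df <- narrowpeak(chrom = m[, 1], start = num[, 1], end = num[, 2],
                   name = m[, 4], score = num[, 3], strand = m[, 6],
                   signal = num[, 4], neglog10_p = num[, 5],
                   neglog10_q = num[, 6], summit_offset = num[, 7])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write peaks in narrowPeak format
#'
#' @param peaks narrowPeak data frame.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_narrowpeak(peaks)
  write.table(peaks, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert peaks to a GRanges object
#'
#' Internal plumbing: BED 0-based half-open to GRanges 1-based closed.
#' @param peaks narrowPeak data frame.
#' @return A [GenomicRanges::GRanges] with peak names and summits as metadata.
#' @export
peaks_to_granges <- function(peaks) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = "*")
  S4Vectors::mcols(gr)$name <- peaks$name
  S4Vectors::mcols(gr)$summit <- peak_summit(peaks)
  gr
}

granges_to_peaks <- function(gr, name = NULL) {
  narrowpeak(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = name %||% paste0("peak_", seq_along(gr)))
}
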