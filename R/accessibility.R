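#' Merge replicate peaks into a consensus set
#'
#' Intervals from all replicates are unioned (merged on >= 1 bp overlap);
#' a merged peak is retained when peaks from at least `min_support`
#' replicates overlap it (a reproducibility filter standing in for rank
#' based replicate-consistency methods). Merged peaks lose the caller
#' summit; the consensus summit is the interval midpoint.
#'
#' @param replicates list of narrowPeak data frames (one per replicate).
#' @param min_support minimum number of supporting replicates (default 2).
#' @param population label stored on the result ("A", "B" or "pooled").
#' @return narrowPeak data frame with a `support` column and a
#'   `population` attribute; peaks are non-overlapping and sorted.
#' @export
merge_replicate_peaks <- function(replicates, min_support = 2,
                                  population = "pooled") {
  assert_that(length(replicates) >= 1, "need at least one replicate")
  assert_that(min_support <= length(replicates),
              "min_support (%d) exceeds number of replicates (%d)",
              min_support, length(replicates))
  grl <- lapply(replicates, peaks_to_granges)
  merged <- GenomicRanges::reduce(do.call(c, unname(grl)))
  support <- Reduce(`+`, lapply(grl, function(g)
    as.integer(GenomicRanges::countOverlaps(merged, g) > 0)))
  keep <- support >= min_support
  merged <- merged[keep]
  out <- granges_to_peaks(merged,
                          name = sprintf("%s_consensus_%05d",
                                         population, seq_len(sum(keep))))
  out$summit_offset <- (out$end - out$start) %/% 2L
  out$support <- support[keep]
  attr(out, "population") <- population
  out
}

#' Classify pooled peaks as shared or population-exclusive
#'
#' Builds the union consensus over the two populations' consensus sets and
#' labels every pooled peak `shared` (overlapped by both), `exclusive_A`
#' or `exclusive_B` (presence/absence on >= 1 bp overlap). Class counts
#' always sum to the pooled total.
#'
#' @param consensus_A,consensus_B consensus narrowPeak data frames from
#'   [merge_replicate_peaks()].
#' @return List of class `peak_classification`: `peaks` (pooled narrowPeak
#'   data frame), `class` (per pooled peak), `counts`, `fractions`.
#' @export
classify_peaks <- function(consensus_A, consensus_B) {
  grA <- peaks_to_granges(consensus_A)
  grB <- peaks_to_granges(consensus_B)
  pooled <- GenomicRanges::reduce(c(grA, grB))
  assert_that(length(pooled) > 0, "empty pooled consensus set")
  inA <- GenomicRanges::countOverlaps(pooled, grA) > 0
  inB <- GenomicRanges::countOverlaps(pooled, grB) > 0
  class <- ifelse(inA & inB, "shared", ifelse(inA, "exclusive_A", "exclusive_B"))
  peaks <- granges_to_peaks(pooled, name = sprintf("pooled_%05d",
                                                   seq_along(pooled)))
  peaks$summit_offset <- (peaks$end - peaks$start) %/% 2L
  counts <- c(shared = sum(class == "shared"),
              exclusive_A = sum(class == "exclusive_A"),
              exclusive_B = sum(class == "exclusive_B"))
  stopifnot(sum(counts) == length(pooled))   # conservation invariant
  structure(list(peaks = peaks, class = class, counts = counts,
                 fractions = counts / length(pooled)),
            class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  cat(sprintf(
    "peak classification: %d pooled peaks (%.1f%% shared, %.1f%% exclusive A, %.1f%% exclusive B)\n",
    sum(x$counts), 100 * x$fractions[1], 100 * x$fractions[2],
    100 * x$fractions[3]))
  invisible(x)
}

#' Count table over pooled consensus peaks
#'
#' Two input modes. With `counts` + `loci`, precomputed per-locus counts
#' are transferred to the pooled peaks that overlap each locus (summing
#' when a pooled peak spans several loci). With `fragments`, a list (per
#' sample) of interval data frames is counted by fragment-midpoint
#' containment; fragments on unknown chromosomes are skipped with a
#' warning.
#'
#' @param pooled pooled narrowPeak data frame (e.g. from
#'   [classify_peaks()]`$peaks`).
#' @param counts optional [count_table()] keyed by locus id.
#' @param loci optional data frame peak_id, chrom, start, end matching
#'   `counts` rows.
#' @param fragments optional named list (sample -> data frame with chrom,
#'   start, end) plus `group` labels.
#' @param group group labels for fragment mode.
#' @return [count_table()] keyed by pooled peak name.
#' @export
count_reads_in_peaks <- function(pooled, counts = NULL, loci = NULL,
                                 fragments = NULL, group = NULL) {
  gr <- peaks_to_granges(pooled)
  if (!is.null(counts)) {
    assert_that(!is.null(loci), "precomputed mode needs `loci` coordinates")
    lgr <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$start + 1L, loci$end))
    hits <- GenomicRanges::findOverlaps(gr, lgr)
    m <- matrix(0, nrow(pooled), ncol(counts$counts),
                dimnames = list(pooled$name, colnames(counts$counts)))
    idx <- match(loci$peak_id[S4Vectors::subjectHits(hits)],
                 rownames(counts$counts))
    q <- S4Vectors::queryHits(hits)
    if (length(q) > 0) {
      agg <- rowsum(counts$counts[idx, , drop = FALSE], group = q)
      m[as.integer(rownames(agg)), ] <- agg
    }
    return(count_table(m, counts$group))
  }
  assert_that(!is.null(fragments) && !is.null(group),
              "fragment mode needs `fragments` and `group`")
  m <- matrix(0, nrow(pooled), length(fragments),
              dimnames = list(pooled$name, names(fragments)))
  for (s in names(fragments)) {
    fr <- fragments[[s]]
    known <- fr$chrom %in% unique(pooled$chrom)
    if (any(!known)) {
      warning(sprintf("%d fragments on unknown chromosomes skipped in %s",
                      sum(!known), s))
      fr <- fr[known, , drop = FALSE]
    }
    mid <- (fr$start + fr$end) %/% 2L
    pts <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
    m[, s] <- GenomicRanges::countOverlaps(gr, pts)
  }
  count_table(m, group)
}

#' Differential accessibility between populations
#'
#' The moderated NB Wald engine ([nb_wald_test()]) applied to peak counts.
#' Emits MA quantities (`M` = log2fc A over B, `A` = mean log2 normalized
#' count) and the significant set at `fdr <= fdr_threshold` with an
#' optional absolute fold-change filter.
#'
#' @param x peak [count_table()].
#' @param factors size factors; median-of-ratios when NULL.
#' @param fdr_threshold FDR cut for the significant set (default 0.10).
#' @param lfc_filter require `|log2fc| >= lfc_filter` (default 0 = off).
#' @return `differential_result` data frame with extra columns M, A,
#'   significant.
#' @export
differential_accessibility <- function(x, factors = NULL, fdr_threshold = 0.10,
                                       lfc_filter = 0) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(x)
  res <- nb_wald_test(x, factors)
  norm <- normalize_counts(x, factors)
  res$M <- res$log2fc
  res$A <- rowMeans(log2(norm + 1))
  res$significant <- !is.na(res$fdr) & res$fdr <= fdr_threshold &
    (lfc_filter == 0 | abs(res$log2fc) >= lfc_filter)
  res
}

#' Annotate peaks with their nearest TSS
#'
#' Nearest gene by absolute summit-to-TSS distance within `window` bp
#' (ties broken by the lexicographically smaller gene_id). The signed
#' distance is negative when the summit lies upstream of the TSS relative
#' to the gene's strand. Category: `tss_proximal` when
#' `|distance| <= tss_margin`, else `genic` when the summit falls inside
#' any gene body, else `intergenic`.
#'
#' @param peaks narrowPeak data frame.
#' @param genes gene table (see [gene_table()]).
#' @param window annotation window around the summit (default 150 kb).
#' @param tss_margin TSS-proximal margin (default 1 kb).
#' @return Data frame: peak_id, nearest_gene (NA when none in window),
#'   distance (signed), category.
#' @export
annotate_peaks <- function(peaks, genes, window = 150000L, tss_margin = 1000L) {
  summit <- peak_summit(peaks)
  n <- nrow(peaks)
  nearest <- rep(NA_character_, n)
  sdist <- rep(NA_integer_, n)
  # genic: summit inside any gene body
  gb <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  pts <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(summit + 1L, summit + 1L))
  genic <- GenomicRanges::countOverlaps(pts, gb) > 0
  for (chrom in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (length(gi) == 0) next
    # per unique TSS keep the lexicographically smallest gene_id upfront
    ord <- gi[order(genes$tss[gi], genes$gene_id[gi])]
    tss <- genes$tss[ord]
    first <- !duplicated(tss)
    utss <- tss[first]
    ugene <- ord[first]
    s <- summit[pi]
    i <- findInterval(s, utss)
    li <- pmax(i, 1L)
    ri <- pmin(i + 1L, length(utss))
    dl <- ifelse(i >= 1, abs(s - utss[li]), Inf)
    dr <- ifelse(i < length(utss), abs(utss[ri] - s), Inf)
    pickl <- dl < dr | (dl == dr &
                          genes$gene_id[ugene[li]] <= genes$gene_id[ugene[ri]])
    best <- ifelse(pickl, ugene[li], ugene[ri])
    dist <- pmin(dl, dr)
    ok <- is.finite(dist) & dist <= window
    nearest[pi[ok]] <- genes$gene_id[best[ok]]
    bt <- genes$tss[best[ok]]
    bs <- genes$strand[best[ok]]
    sdist[pi[ok]] <- as.integer(ifelse(bs == "+", s[ok] - bt, bt - s[ok]))
  }
  category <- ifelse(!is.na(sdist) & abs(sdist) <= tss_margin, "tss_proximal",
                     ifelse(genic, "genic", "intergenic"))
  data.frame(peak_id = peaks$name, nearest_gene = nearest, distance = sdist,
             category = category, stringsAsFactors = FALSE)
}

#' TSS over-representation between exclusive peak classes
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table
#' \[tss_proximal vs not\] x \[A-exclusive vs B-exclusive\].
#'
#' @param annot_A,annot_B annotation data frames (from [annotate_peaks()])
#'   for the A-exclusive and B-exclusive peaks.
#' @return List: table, odds_ratio, p.
#' @export
tss_overrepresentation <- function(annot_A, annot_B) {
  assert_that(nrow(annot_A) > 0 && nrow(annot_B) > 0,
              "both annotation sets must be non-empty")
  a <- sum(annot_A$category == "tss_proximal")
  b <- nrow(annot_A) - a
  c_ <- sum(annot_B$category == "tss_proximal")
  d <- nrow(annot_B) - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("A_exclusive", "B_exclusive"),
                                c("tss_proximal", "other")))
  ft <- fisher_exact_greater(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}
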