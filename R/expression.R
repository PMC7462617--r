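#' Median-of-ratios size factors
#'
#' Per sample, the factor is the median over genes (restricted to genes
#' with a positive count in every sample) of the ratio of the gene's count
#' to its geometric mean across samples. Factors are invariant under gene
#' reordering and scale-equivariant: multiplying one sample's counts by a
#' constant multiplies its factor by the same constant.
#'
#' @param x [count_table()].
#' @return Named numeric vector of size factors (> 0).
#' @export
size_factors_median_of_ratios <- function(x) {
  counts <- x$counts
  pos <- rowSums(counts > 0) == ncol(counts)
  assert_that(any(pos),
    "no gene has positive counts in every sample; median-of-ratios undefined (consider a pseudo-reference fallback)")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)                      # log geometric mean
  factors <- apply(logc, 2, function(col) exp(median(col - ref)))
  stats::setNames(as.numeric(factors), colnames(counts))
}

#' Drop genes with null expression
#'
#' Removes genes whose count is zero in every sample; genes with any
#' non-zero count are retained (row-wise removal keeps the table
#' rectangular).
#'
#' @param x [count_table()].
#' @return Filtered [count_table()]; warns when everything is removed.
#' @export
filter_null_expression <- function(x) {
  keep <- rowSums(x$counts) > 0
  if (!any(keep)) warning("all genes have null expression; empty table returned")
  count_table(x$counts[keep, , drop = FALSE], x$group)
}

#' Detection threshold from intergenic background windows
#'
#' Computes, per sample, the nearest-rank percentile (index
#' `ceiling(q/100 * n)` of the sorted values) of `log2(count / factor + 1)`
#' over intergenic windows; the pooled threshold is the maximum over
#' samples (conservative detection).
#'
#' @param intergenic [count_table()] of window counts.
#' @param factors named size factors (from the gene table of the same
#'   samples).
#' @param percentile percentile in (0, 100]; default 95.
#' @return List of class `detection_threshold` with `value` (pooled),
#'   `per_sample`, `percentile`, `n_windows`.
#' @export
detection_threshold <- function(intergenic, factors, percentile = 95) {
  assert_that(nrow(intergenic$counts) > 0, "no intergenic windows")
  assert_that(percentile > 0 && percentile <= 100,
              "percentile must be in (0, 100]")
  norm <- log2(normalize_counts(intergenic, factors) + 1)
  k <- ceiling(percentile / 100 * nrow(norm))
  per_sample <- apply(norm, 2, function(col) sort(col)[k])
  structure(list(value = max(per_sample), per_sample = per_sample,
                 percentile = percentile, n_windows = nrow(norm)),
            class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf(
    "detection threshold: %.4f log2(normalized count + 1) (p%g over %d windows)\n",
    x$value, x$percentile, x$n_windows))
  invisible(x)
}

#' Partition genes into expressed sets per population
#'
#' A gene is called expressed in a population when the mean over that
#' population's replicates of `log2(normalized count + 1)` strictly
#' exceeds the detection threshold. Returns the Venn partition of the two
#' expressed sets.
#'
#' @param x gene [count_table()].
#' @param factors size factors.
#' @param threshold a `detection_threshold` (or numeric scalar on the same
#'   scale).
#' @return List of class `expression_partition` with `expressed_A`,
#'   `expressed_B`, `shared`, `specific_A`, `specific_B` gene-id vectors.
#' @export
partition_expressed <- function(x, factors, threshold) {
  thr <- if (inherits(threshold, "detection_threshold")) threshold$value
         else as.numeric(threshold)
  iA <- samples_of(x, "A")
  iB <- samples_of(x, "B")
  assert_that(length(iA) > 0 && length(iB) > 0,
              "both populations need at least one sample")
  norm <- log2(normalize_counts(x, factors) + 1)
  mA <- rowMeans(norm[, iA, drop = FALSE])
  mB <- rowMeans(norm[, iB, drop = FALSE])
  expressed_A <- rownames(x$counts)[mA > thr]
  expressed_B <- rownames(x$counts)[mB > thr]
  structure(list(expressed_A = expressed_A, expressed_B = expressed_B,
                 shared = intersect(expressed_A, expressed_B),
                 specific_A = setdiff(expressed_A, expressed_B),
                 specific_B = setdiff(expressed_B, expressed_A),
                 threshold = thr),
            class = "expression_partition")
}

#' @export
print.expression_partition <- function(x, ...) {
  cat(sprintf(
    "expression partition: %d shared, %d specific to A, %d specific to B (threshold %.3f)\n",
    length(x$shared), length(x$specific_A), length(x$specific_B), x$threshold))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotone enforcement, capped at 1, input order
#' preserved (thin wrapper over `stats::p.adjust`, kept as the package's
#' single multiple-testing entry point).
#'
#' @param p p-values in \[0, 1\].
#' @return Adjusted p-values (same length/order).
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression between populations A and B
#'
#' Moderated negative binomial Wald test (see [nb_wald_test()]) on
#' normalized counts, fold changes oriented A over B, BH adjustment over
#' all tested genes. Also reports the two call sets used downstream:
#' `adjusted p < 0.05` and `|log2fc| >= 1 & fdr <= 0.01`.
#'
#' @param x gene [count_table()].
#' @param factors size factors; computed by median-of-ratios when NULL.
#' @param alpha_adj_p threshold for the adjusted-p call set.
#' @param volcano_lfc,volcano_fdr thresholds for the fold-change call set.
#' @return Data frame of class `differential_result`: feature_id,
#'   base_mean, log2fc, p, fdr, flag, sig_adj_p, sig_volcano.
#' @export
differential_expression <- function(x, factors = NULL, alpha_adj_p = 0.05,
                                    volcano_lfc = 1, volcano_fdr = 0.01) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(x)
  res <- nb_wald_test(x, factors)
  res$sig_adj_p <- !is.na(res$fdr) & res$fdr < alpha_adj_p
  res$sig_volcano <- !is.na(res$fdr) & abs(res$log2fc) >= volcano_lfc &
    res$fdr <= volcano_fdr
  res
}
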