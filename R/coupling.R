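#' Joint accessibility-expression coupling classification
#'
#' Links each annotated peak to its nearest gene and classifies it by the
#' joint differential outcome at a common FDR threshold:
#'
#' * `concordant_A`: both FDRs below threshold, both log ratios > 0
#'   (more open and more expressed in population A);
#' * `concordant_B`: both significant, both ratios < 0;
#' * `discordant`: both significant, strictly opposite signs;
#' * `not_significant`: everything else with an assigned gene (a log
#'   ratio of exactly 0 carries no direction and is never called
#'   concordant or discordant);
#' * `unassigned`: no gene within the annotation window.
#'
#' @param annotations data frame from [annotate_peaks()].
#' @param da `differential_result` keyed by peak (accessibility).
#' @param de `differential_result` keyed by gene (expression).
#' @param fdr_threshold common significance threshold (default 0.1).
#' @return Data frame of class `coupling_result`: peak_id, gene_id,
#'   atac_log_ratio, rna_log_ratio, atac_fdr, rna_fdr, klass; class
#'   counts in the `counts` attribute.
#' @export
couple <- function(annotations, da, de, fdr_threshold = 0.1) {
  missing <- setdiff(annotations$peak_id, da$feature_id)
  assert_that(length(missing) == 0,
              "peaks missing from the accessibility results: %s",
              paste(head(missing, 5), collapse = ", "))
  ia <- match(annotations$peak_id, da$feature_id)
  ig <- match(annotations$nearest_gene, de$feature_id)
  atac_lr <- da$log2fc[ia]
  atac_fdr <- da$fdr[ia]
  rna_lr <- de$log2fc[ig]
  rna_fdr <- de$fdr[ig]
  assigned <- !is.na(annotations$nearest_gene) & !is.na(ig)
  both_sig <- assigned & !is.na(atac_fdr) & !is.na(rna_fdr) &
    atac_fdr < fdr_threshold & rna_fdr < fdr_threshold
  klass <- ifelse(!assigned, "unassigned",
           ifelse(both_sig & atac_lr > 0 & rna_lr > 0, "concordant_A",
           ifelse(both_sig & atac_lr < 0 & rna_lr < 0, "concordant_B",
           ifelse(both_sig & ((atac_lr > 0 & rna_lr < 0) |
                                (atac_lr < 0 & rna_lr > 0)), "discordant",
                  "not_significant"))))
  res <- data.frame(peak_id = annotations$peak_id,
                    gene_id = ifelse(assigned, annotations$nearest_gene,
                                     NA_character_),
                    atac_log_ratio = atac_lr, rna_log_ratio = rna_lr,
                    atac_fdr = atac_fdr, rna_fdr = rna_fdr, klass = klass,
                    stringsAsFactors = FALSE)
  lev <- c("concordant_A", "concordant_B", "discordant", "not_significant",
           "unassigned")
  attr(res, "counts") <- table(factor(klass, levels = lev))
  class(res) <- c("coupling_result", "data.frame")
  res
}

#' Coupling class counts
#' @param records `coupling_result` from [couple()].
#' @return Named integer vector of class counts.
#' @export
coupling_summary <- function(records) {
  cnt <- attr(records, "counts")
  if (is.null(cnt)) {
    lev <- c("concordant_A", "concordant_B", "discordant", "not_significant",
             "unassigned")
    cnt <- table(factor(records$klass, levels = lev))
  }
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Scatter table of coupling log ratios
#'
#' One row per assigned peak with exactly the plotted quantities: change
#' in accessibility (x) versus change in nearest-gene expression (y).
#'
#' @param records `coupling_result` from [couple()].
#' @return Data frame: peak_id, x (atac log ratio), y (rna log ratio),
#'   klass.
#' @export
coupling_scatter_table <- function(records) {
  keep <- records$klass != "unassigned"
  data.frame(peak_id = records$peak_id[keep],
             x = records$atac_log_ratio[keep],
             y = records$rna_log_ratio[keep],
             klass = records$klass[keep], stringsAsFactors = FALSE)
}
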