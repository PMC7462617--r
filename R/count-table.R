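#' Count tables with population labels
#'
#' A `count_table` is the shared container of the RNA and ATAC branches: a
#' non-negative integer matrix (features x samples) plus a group label
#' (`A` or `B`) for every sample.
#'
#' @param counts integer matrix with rownames = feature ids and colnames =
#'   sample ids.
#' @param group character/factor vector of "A"/"B", one per sample, or a
#'   named vector matched against colnames.
#' @return An object of class `count_table` (list with `counts`, `group`).
#' @export
count_table <- function(counts, group) {
  assert_that(is.matrix(counts), "count_table: counts must be a matrix")
  assert_that((nrow(counts) == 0 || !is.null(rownames(counts))) &&
                !is.null(colnames(counts)),
              "count_table: counts needs feature rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(counts)), "count_table: duplicated feature ids")
  assert_that(!anyDuplicated(colnames(counts)), "count_table: duplicated sample ids")
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == round(counts)),
              "count_table: counts must be non-negative integers")
  if (!is.null(names(group))) {
    assert_that(all(colnames(counts) %in% names(group)),
                "count_table: group labels missing for some samples")
    group <- group[colnames(counts)]
  }
  assert_that(length(group) == ncol(counts),
              "count_table: one group label per sample required")
  group <- as.character(group)
  assert_that(all(group %in% c("A", "B")), "count_table: groups must be 'A' or 'B'")
  structure(list(counts = matrix(as.numeric(counts), nrow(counts), ncol(counts),
                                 dimnames = dimnames(counts)),
                 group = stats::setNames(group, colnames(counts))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (A: %d, B: %d)\n",
              nrow(x$counts), ncol(x$counts), sum(x$group == "A"),
              sum(x$group == "B")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Samples belonging to one population
#' @param x count_table.
#' @param group "A" or "B".
#' @return Character vector of sample ids.
#' @export
samples_of <- function(x, group) names(x$group)[x$group == group]

#' Read a count table from TSV
#'
#' First column = feature id, remaining columns = samples (header row).
#' Group labels are taken from a `group` argument or inferred from sample
#' names of the form `A_rep1`, `B_rep2`, ...
#'
#' @param path TSV file.
#' @param group optional named group vector.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, group = NULL) {
  assert_that(file.exists(path), "count table not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "count table needs a feature column plus samples: %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (is.null(group)) {
    pref <- sub("_.*$", "", colnames(m))
    assert_that(all(pref %in% c("A", "B")),
                "cannot infer groups from sample names in %s; pass `group`", path)
    group <- stats::setNames(pref, colnames(m))
  }
  count_table(m, group)
}

#' Write a count table to TSV
#' @param x count_table.
#' @param path output path.
#' @param feature_col name of the feature-id column.
#' @export
write_count_table <- function(x, path, feature_col = "feature_id") {
  df <- data.frame(rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize counts by size factors
#' @param x count_table.
#' @param factors named numeric vector of per-sample size factors.
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(x, factors) {
  assert_that(all(colnames(x$counts) %in% names(factors)),
              "size factors missing for some samples")
  sweep(x$counts, 2, factors[colnames(x$counts)], "/")
}
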