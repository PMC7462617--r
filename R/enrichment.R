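#' One-sided (greater) Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric upper tail `P(X >= a)` for the table
#' `rbind(c(a, b), c(c, d))`, enrichment of the top-left cell. The odds
#' ratio is the sample odds ratio `ad/bc` (`Inf` when `bc = 0` and
#' `ad > 0`, `NaN` when both products are 0).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_greater <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "table must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "table cells must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c_ > 0) (a * d) / (b * c_)
        else if (a * d > 0) Inf else NaN
  list(odds_ratio = or, p = min(1, p))
}

#' Extract summit-centred sequences for peaks
#'
#' One sequence of length `2 * flank` per peak, centred on the summit
#' (interval midpoint when no summit was recorded), upper-cased. Windows
#' running off a chromosome end are truncated and flagged.
#'
#' @param peaks narrowPeak data frame.
#' @param genome named character vector of chromosome sequences.
#' @param flank half-width in bp (default 200, i.e. 400 bp windows).
#' @return Named character vector of sequences (names = peak names) with a
#'   logical `truncated` attribute.
#' @export
extract_summit_sequences <- function(peaks, genome, flank = 200L) {
  missing <- setdiff(unique(peaks$chrom), names(genome))
  assert_that(length(missing) == 0, "peaks on unknown chromosome: %s",
              paste(missing, collapse = ", "))
  summit <- peak_summit(peaks)
  start <- summit - flank
  end <- summit + flank
  lens <- nchar(genome)[peaks$chrom]
  truncated <- start < 0 | end > lens
  seqs <- vapply(seq_len(nrow(peaks)), function(i)
    genome_slice(genome, peaks$chrom[i], start[i], end[i]), character(1))
  names(seqs) <- peaks$name
  attr(seqs, "truncated") <- stats::setNames(truncated, peaks$name)
  seqs
}

#' Sample random background sequences from the genome
#'
#' Start positions are uniform over all positions admitting a full
#' window (chromosomes weighted by usable length); windows with more than
#' `max_n_fraction` ambiguous bases are rejected and resampled.
#' Deterministic given `seed`.
#'
#' @param genome named character vector.
#' @param n number of sequences (default 20,000).
#' @param length window length (default 400 bp).
#' @param seed RNG seed.
#' @param max_n_fraction maximum tolerated fraction of non-ACGT bases.
#' @param max_tries resampling budget multiplier.
#' @param match_gc_to optional character vector of target sequences; when
#'   given, background windows are accepted so that their GC distribution
#'   matches the targets' (decile-binned), instead of plain uniform
#'   sampling. Off by default.
#' @return Named character vector (`bg_000001`, ...) of `n` sequences.
#' @export
sample_background <- function(genome, n = 20000L, length = 400L, seed = 1L,
                              max_n_fraction = 0.1, max_tries = 10L,
                              match_gc_to = NULL) {
  usable <- nchar(genome) - length + 1
  assert_that(any(usable > 0), "no chromosome admits a %d bp window", length)
  usable <- pmax(usable, 0)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  set.seed(seed)
  gc_of <- function(s) nchar(gsub("[^GC]", "", s)) / pmax(1, nchar(s))
  breaks <- NULL
  quota <- NULL
  if (!is.null(match_gc_to)) {
    breaks <- unique(quantile(gc_of(match_gc_to), seq(0, 1, 0.1)))
    breaks[1] <- -Inf
    breaks[base::length(breaks)] <- Inf
    tgt <- table(cut(gc_of(match_gc_to), breaks))
    quota <- largest_remainder(n, as.numeric(tgt) / sum(tgt))
  }
  out <- character(0)
  tries <- 0L
  while (base::length(out) < n && tries < max_tries) {
    need <- (n - base::length(out)) * if (is.null(quota)) 1L else 10L
    if (!is.null(quota)) need <- max(need, 2000L)
    chrom <- sample(names(genome), need, replace = TRUE, prob = usable)
    pos <- floor(runif(need) * usable[chrom])   # 0-based start
    seqs <- vapply(seq_len(need), function(i)
      genome_slice(genome, chrom[i], pos[i], pos[i] + length), character(1))
    frac_n <- 1 - (nchar(gsub("[^ACGT]", "", seqs)) / nchar(seqs))
    seqs <- seqs[frac_n <= max_n_fraction]
    if (!is.null(quota)) {
      bins <- as.integer(cut(gc_of(seqs), breaks))
      keep <- logical(base::length(seqs))
      for (b in seq_along(quota)) {
        idx <- which(bins == b)
        take <- min(quota[b], base::length(idx))
        keep[idx[seq_len(take)]] <- TRUE
        quota[b] <- quota[b] - take
      }
      seqs <- seqs[keep]
    }
    out <- c(out, seqs)
    tries <- tries + 1L
  }
  assert_that(base::length(out) >= n || (!is.null(quota) && sum(quota) == 0),
              "could not collect %d background windows within the retry budget", n)
  stats::setNames(out[seq_len(n)], sprintf("bg_%06d", seq_len(n)))
}

#' Single-motif enrichment in peak vs background sequences
#'
#' Per motif, presence is binarized per sequence (>= 1 hit); the 2x2 table
#' (peak vs background) x (present vs absent) is tested with the
#' one-sided (greater) Fisher test and BH-adjusted over motifs.
#'
#' @param peak_seqs,background named character vectors of sequences.
#' @param pwms list of [pwm()] objects.
#' @param threshold_fraction scanner hit threshold.
#' @return Data frame: motif_id, k_peak, n_peak, k_bg, n_bg, odds_ratio,
#'   p, fdr, sorted by p.
#' @export
single_motif_enrichment <- function(peak_seqs, background, pwms,
                                    threshold_fraction = 0.8) {
  assert_that(length(peak_seqs) > 0 && length(background) > 0,
              "both sequence sets must be non-empty")
  sp <- scan_sequences(peak_seqs, pwms, threshold_fraction)
  sb <- scan_sequences(background, pwms, threshold_fraction)
  k_peak <- colSums(sp$presence)
  k_bg <- colSums(sb$presence)
  n_peak <- length(peak_seqs)
  n_bg <- length(background)
  tests <- lapply(seq_along(pwms), function(i)
    fisher_exact_greater(matrix(c(k_peak[i], n_peak - k_peak[i],
                                  k_bg[i], n_bg - k_bg[i]), 2, 2, byrow = TRUE)))
  res <- data.frame(
    motif_id = vapply(pwms, function(p) p$motif_id, character(1)),
    k_peak = as.integer(k_peak), n_peak = n_peak,
    k_bg = as.integer(k_bg), n_bg = n_bg,
    odds_ratio = vapply(tests, `[[`, numeric(1), "odds_ratio"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  res$fdr <- bh_adjust(res$p)
  res[order(res$p, res$motif_id), , drop = FALSE]
}

#' All unordered motif combinations of a given order
#'
#' @param motif_ids character vector of distinct motif ids.
#' @param order combination size (default 3).
#' @return List of sorted character tuples in lexicographic order.
#' @export
generate_combinations <- function(motif_ids, order = 3L) {
  motif_ids <- unique(motif_ids)
  assert_that(length(motif_ids) >= order,
              "need at least %d distinct motifs (got %d)", order,
              length(motif_ids))
  m <- combn(sort(motif_ids), order)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Is a motif combination present within a span?
#'
#' TRUE when the sequence carries at least one hit of every motif in
#' `triple` such that the union of the chosen hits' covered positions
#' fits inside a window of `span` bp (`max end - min start <= span`).
#' For sequences no longer than `span` this reduces to co-presence.
#'
#' @param hits data frame of hits for ONE sequence (motif_id, offset).
#' @param triple character vector of distinct motif ids.
#' @param span window size in bp (default 500).
#' @param motif_lengths named integer vector of motif lengths.
#' @return Logical scalar.
#' @export
combination_present <- function(hits, triple, span = 500L, motif_lengths) {
  assert_that(!anyDuplicated(triple), "combination contains a repeated motif id")
  per <- lapply(triple, function(m) {
    h <- hits[hits$motif_id == m, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    cbind(start = h$offset, end = h$offset + motif_lengths[[m]])
  })
  if (any(vapply(per, is.null, logical(1)))) return(FALSE)
  # small hit lists: enumerate all choices
  grid <- expand.grid(lapply(per, function(m) seq_len(nrow(m))))
  for (r in seq_len(nrow(grid))) {
    s <- vapply(seq_along(per), function(k) per[[k]][grid[r, k], "start"], numeric(1))
    e <- vapply(seq_along(per), function(k) per[[k]][grid[r, k], "end"], numeric(1))
    if (max(e) - min(s) <= span) return(TRUE)
  }
  FALSE
}

# presence matrix (sequences x combinations) from one cached scanning pass
combination_presence_matrix <- function(scan, combos, span, motif_lengths,
                                        seq_len_max) {
  pres <- scan$presence
  n_seq <- nrow(pres)
  out <- matrix(FALSE, n_seq, length(combos),
                dimnames = list(rownames(pres), NULL))
  co_presence <- seq_len_max <= span
  idx <- lapply(combos, function(tr) match(tr, colnames(pres)))
  if (co_presence) {
    for (j in seq_along(combos)) {
      out[, j] <- Reduce(`&`, lapply(idx[[j]], function(k) pres[, k]))
    }
    return(out)
  }
  hits_by_seq <- split(scan$hits, factor(scan$hits$seq_id, levels = rownames(pres)))
  for (si in seq_len(n_seq)) {
    h <- hits_by_seq[[si]]
    for (j in seq_along(combos)) {
      if (all(pres[si, idx[[j]]])) {
        out[si, j] <- combination_present(h, combos[[j]], span, motif_lengths)
      }
    }
  }
  out
}

#' Order-k motif combination co-occurrence enrichment
#'
#' Scans peak and background sequences once per (sequence, motif), forms
#' every order-`order` combination, binarizes combination presence per
#' sequence under the `span` rule, and tests each combination's peak vs
#' background presence with the one-sided (greater) Fisher test,
#' BH-adjusted over all combinations. Results are sorted by p.
#'
#' @param peak_seqs,background named character vectors.
#' @param pwms list of [pwm()] objects.
#' @param order combination order (default 3).
#' @param span co-occurrence span in bp (default 500).
#' @param threshold_fraction scanner hit threshold.
#' @return Data frame: motif_1..motif_k, k_peak, n_peak, k_bg, n_bg,
#'   odds_ratio, p, fdr, rank.
#' @export
combination_enrichment <- function(peak_seqs, background, pwms, order = 3L,
                                   span = 500L, threshold_fraction = 0.8) {
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  assert_that(order <= length(ids), "order (%d) exceeds motif count (%d)",
              order, length(ids))
  combos <- generate_combinations(ids, order)
  motif_lengths <- stats::setNames(vapply(pwms, pwm_length, integer(1)), ids)
  sp <- scan_sequences(peak_seqs, pwms, threshold_fraction)
  sb <- scan_sequences(background, pwms, threshold_fraction)
  mp <- combination_presence_matrix(sp, combos, span, motif_lengths,
                                    max(nchar(peak_seqs)))
  mb <- combination_presence_matrix(sb, combos, span, motif_lengths,
                                    max(nchar(background)))
  k_peak <- colSums(mp)
  k_bg <- colSums(mb)
  n_peak <- length(peak_seqs)
  n_bg <- length(background)
  tests <- lapply(seq_along(combos), function(j)
    fisher_exact_greater(matrix(c(k_peak[j], n_peak - k_peak[j],
                                  k_bg[j], n_bg - k_bg[j]), 2, 2, byrow = TRUE)))
  tuples <- do.call(rbind, combos)
  res <- data.frame(tuples, stringsAsFactors = FALSE)
  names(res) <- paste0("motif_", seq_len(order))
  res$k_peak <- as.integer(k_peak); res$n_peak <- n_peak
  res$k_bg <- as.integer(k_bg); res$n_bg <- n_bg
  res$odds_ratio <- vapply(tests, `[[`, numeric(1), "odds_ratio")
  res$p <- vapply(tests, `[[`, numeric(1), "p")
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, -res$odds_ratio), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
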