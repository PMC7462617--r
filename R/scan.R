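#' Reverse complement of a DNA string
#' @param seq character scalar over ACGTN.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "")[[1]]),
        collapse = "")
}

# integer encoding A=1 C=2 G=3 T=4, N (or anything else) = 5
encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

# scores at every offset of one strand; column 5 scores -Inf (ambiguous base)
scan_scores <- function(enc, lo) {
  L <- nrow(lo)
  S <- length(enc)
  if (S < L) return(numeric(0))
  lo5 <- cbind(lo, -Inf)
  n_off <- S - L + 1L
  total <- numeric(n_off)
  for (i in seq_len(L)) {
    total <- total + lo5[i, enc[i:(i + n_off - 1L)]]
  }
  total
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2-odds scoring `sum_i log2(probs[i, base] / background[base])` at
#' every offset on the forward sequence and its reverse complement; an
#' offset is a hit when its score reaches `threshold_fraction` times the
#' maximum attainable score. Ambiguous bases (N) score `-Inf` at their
#' column. Reverse-strand hits are reported with their offset on the
#' forward coordinate system (leftmost base of the matched window).
#'
#' @param seq character scalar over ACGTN.
#' @param pwm a [pwm()].
#' @param threshold_fraction hit threshold as a fraction of the maximum
#'   score, in (0, 1\].
#' @param seq_id id recorded in the output.
#' @return Data frame: seq_id, motif_id, offset (0-based), strand, score.
#' @export
scan_sequence <- function(seq, pwm, threshold_fraction = 0.8, seq_id = "seq") {
  assert_that(threshold_fraction > 0 && threshold_fraction <= 1,
              "threshold_fraction must be in (0, 1]")
  lo <- pwm_logodds(pwm)
  thr <- threshold_fraction * pwm_max_score(pwm)
  enc <- encode_seq(seq)
  L <- nrow(lo)
  fwd <- scan_scores(enc, lo)
  rev_enc <- rev(5L - enc)          # complement of A..T is T..A; N stays 5
  rev_enc[rev_enc == 0L] <- 5L
  rvs <- scan_scores(rev_enc, lo)
  hit_f <- which(fwd >= thr)
  hit_r <- which(rvs >= thr)
  S <- length(enc)
  n_hits <- length(hit_f) + length(hit_r)
  data.frame(
    seq_id = rep_len(seq_id, n_hits),
    motif_id = rep_len(pwm$motif_id, n_hits),
    offset = c(hit_f - 1L, S - L + 1L - hit_r),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rvs[hit_r]),
    stringsAsFactors = FALSE)
}

#' Scan many sequences with many PWMs once
#'
#' The shared scanning pass cached by the enrichment operations: every
#' (sequence, motif) pair is scanned exactly once.
#'
#' @param seqs named character vector of sequences.
#' @param pwms list of [pwm()] objects.
#' @param threshold_fraction see [scan_sequence()].
#' @return List with `hits` (one data frame, all hits) and `presence`
#'   (logical matrix sequences x motifs: >= 1 hit).
#' @export
scan_sequences <- function(seqs, pwms, threshold_fraction = 0.8) {
  assert_that(!is.null(names(seqs)), "sequences must be named")
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  los <- lapply(pwms, pwm_logodds)
  thrs <- vapply(pwms, pwm_max_score, numeric(1)) * threshold_fraction
  presence <- matrix(FALSE, length(seqs), length(pwms),
                     dimnames = list(names(seqs), ids))
  out <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    enc <- encode_seq(seqs[[si]])
    rev_enc <- rev(5L - enc)
    rev_enc[rev_enc == 0L] <- 5L
    S <- length(enc)
    per_seq <- vector("list", length(pwms))
    for (mi in seq_along(pwms)) {
      L <- nrow(los[[mi]])
      fwd <- scan_scores(enc, los[[mi]])
      rvs <- scan_scores(rev_enc, los[[mi]])
      hit_f <- which(fwd >= thrs[mi])
      hit_r <- which(rvs >= thrs[mi])
      if (length(hit_f) + length(hit_r) > 0) {
        presence[si, mi] <- TRUE
        per_seq[[mi]] <- data.frame(
          seq_id = names(seqs)[si], motif_id = ids[mi],
          offset = c(hit_f - 1L, S - L + 1L - hit_r),
          strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
          score = c(fwd[hit_f], rvs[hit_r]),
          stringsAsFactors = FALSE)
      }
    }
    out[[si]] <- do.call(rbind, per_seq)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) {
    hits <- data.frame(seq_id = character(0), motif_id = character(0),
                       offset = integer(0), strand = character(0),
                       score = numeric(0), stringsAsFactors = FALSE)
  }
  list(hits = hits, presence = presence)
}
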