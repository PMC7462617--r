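#' Position weight matrices
#'
#' A `pwm` stores a position probability matrix over ACGT together with the
#' background model used for log-odds scoring. Matrices are built from
#' count (PFM) blocks with a pseudocount: `p = (c + pc) / (sum(c) + 4 pc)`
#' per column of the PFM.
#'
#' @param motif_id motif identifier.
#' @param counts L x 4 non-negative matrix of base counts (columns ACGT),
#'   or a probability matrix if `is_probs = TRUE`.
#' @param background length-4 background probabilities (default uniform).
#' @param pseudocount pseudocount added to every cell (default 1).
#' @param is_probs set TRUE when `counts` already holds probabilities.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, counts, background = rep(0.25, 4), pseudocount = 1,
                is_probs = FALSE) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) == 4, "pwm %s: matrix must have 4 columns (ACGT)", motif_id)
  assert_that(nrow(counts) >= 4, "pwm %s: length must be >= 4", motif_id)
  assert_that(all(counts >= 0), "pwm %s: negative cells", motif_id)
  assert_that(length(background) == 4 && abs(sum(background) - 1) < 1e-9 &&
                all(background > 0),
              "pwm %s: background must be 4 positive probabilities summing to 1",
              motif_id)
  if (is_probs) {
    probs <- counts
  } else {
    assert_that(pseudocount > 0 || all(rowSums(counts) > 0),
                "pwm %s: all-zero count row with zero pseudocount", motif_id)
    probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  }
  assert_that(all(abs(rowSums(probs) - 1) < 1e-9),
              "pwm %s: probability rows must sum to 1", motif_id)
  dimnames(probs) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(motif_id = as.character(motif_id), probs = probs,
                 background = as.numeric(background),
                 pseudocount = as.numeric(pseudocount)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, consensus %s\n", x$motif_id,
              nrow(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Motif length
#' @param x pwm.
#' @return Integer number of positions.
#' @export
pwm_length <- function(x) nrow(x$probs)

#' Consensus sequence (most probable base per position)
#' @param x pwm.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$probs, 1, which.max)], collapse = "")
}

#' Per-position log2-odds score matrix
#' @param x pwm.
#' @return L x 4 matrix of log2(p / background).
#' @export
pwm_logodds <- function(x) {
  lo <- log2(sweep(x$probs, 2, x$background, "/"))
  dimnames(lo) <- dimnames(x$probs)
  lo
}

#' Maximum attainable log2-odds score
#' @param x pwm.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(x) sum(apply(pwm_logodds(x), 1, max))

#' Read motifs from a JASPAR-style PFM file
#'
#' Accepts the JASPAR dialects: a `>id name` header followed by either four
#' bracketed rows (`A [ 1 2 3 ]`) or four bare numeric rows, rows ordered
#' A, C, G, T. Counts are converted to probabilities with `pseudocount`.
#'
#' @param path PFM file.
#' @param pseudocount pseudocount for [pwm()].
#' @param background background distribution for [pwm()].
#' @return List of `pwm` objects.
#' @export
read_pfm <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  assert_that(file.exists(path), "PFM file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  assert_that(length(heads) > 0, "no motif headers ('>') in %s", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    assert_that(length(block) == 4, "motif block %d in %s: expected 4 rows, got %d",
                i, path, length(block))
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[", "", l)
      l <- gsub("\\]\\s*$", "", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      assert_that(!anyNA(v), "unparseable PFM row in %s: '%s'", path, l)
      v
    })
    assert_that(length(unique(lengths(rows))) == 1,
                "motif block %d in %s: ragged rows", i, path)
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    # JASPAR rows are per-base; the pwm matrix is positions x bases
    out[[i]] <- pwm(id, t(do.call(rbind, rows)), background = background,
                    pseudocount = pseudocount)
  }
  out
}

#' Write motifs in JASPAR PFM layout
#'
#' Probabilities are written scaled to counts out of `scale` so that a
#' write/read round trip recovers the probabilities.
#'
#' @param pwms list of pwm objects.
#' @param path output path.
#' @param scale integer count total per position.
#' @export
write_pfm <- function(pwms, path, scale = 1000L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$motif_id), con)
    cnt <- p$probs * scale
    for (j in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[j],
                         paste(sprintf("%.10g", cnt[, j]), collapse = " ")), con)
    }
  }
  invisible(path)
}
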