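# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# step-up BH by its definition: adj_i = min over j >= rank(i) of m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# one-sided (greater) Fisher p by hypergeometric enumeration
fisher_oracle <- function(a, b, c_, d) {
  k <- a + b                 # row-1 total (draws)
  m <- a + c_                # successes in population
  n <- b + d
  xs <- a:min(k, m)
  sum(stats::dhyper(xs, m, n, k))
}

# exhaustive PWM scan: per-offset scoring loop on both strands
scan_oracle <- function(seq, pw, threshold_fraction = 0.8) {
  lo <- pwm_logodds(pw)
  L <- nrow(lo)
  thr <- threshold_fraction * pwm_max_score(pw)
  score_at <- function(s, off) {
    tot <- 0
    for (i in seq_len(L)) {
      base <- substr(s, off + i, off + i)
      j <- match(base, c("A", "C", "G", "T"))
      tot <- tot + if (is.na(j)) -Inf else lo[i, j]
    }
    tot
  }
  rows <- list()
  S <- nchar(seq)
  rc <- revcomp(seq)
  for (off in 0:(S - L)) {
    sc <- score_at(seq, off)
    if (sc >= thr) rows[[length(rows) + 1]] <-
        data.frame(offset = off, strand = "+", score = sc)
    sc <- score_at(rc, off)
    if (sc >= thr) rows[[length(rows) + 1]] <-
        data.frame(offset = S - L - off, strand = "-", score = sc)
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$strand, out$offset), , drop = FALSE]
}

# O(n*m) nearest-TSS scan with the documented tie-break
nearest_oracle <- function(peaks, genes, window = 150000, tss_margin = 1000) {
  summit <- peak_summit(peaks)
  res <- data.frame(peak_id = peaks$name, nearest_gene = NA_character_,
                    distance = NA_integer_, category = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    cat_genic <- any(g$start <= summit[i] & summit[i] < g$end)
    if (nrow(g) > 0) {
      d <- abs(summit[i] - g$tss)
      best <- which(d == min(d))
      if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
      if (d[best] <= window) {
        res$nearest_gene[i] <- g$gene_id[best]
        res$distance[i] <- if (g$strand[best] == "+") summit[i] - g$tss[best]
                           else g$tss[best] - summit[i]
      }
    }
    res$category[i] <- if (!is.na(res$distance[i]) &&
                             abs(res$distance[i]) <= tss_margin) "tss_proximal"
                       else if (cat_genic) "genic" else "intergenic"
  }
  res
}

# random DNA of given length
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a sharp PWM whose consensus is the given string
consensus_pwm <- function(id, consensus, p_major = 0.91) {
  bases <- strsplit(consensus, "")[[1]]
  probs <- matrix((1 - p_major) / 3, length(bases), 4)
  for (i in seq_along(bases)) {
    probs[i, match(bases[i], c("A", "C", "G", "T"))] <- p_major
  }
  pwm(id, probs, is_probs = TRUE)
}

# tiny two-population count table with known structure
toy_counts <- function(n_genes = 50, nrep = 3, seed = 1, mu = 100,
                       dispersion = 0.1) {
  set.seed(seed)
  samples <- c(paste0("A_rep", 1:nrep), paste0("B_rep", 1:nrep))
  m <- matrix(rnbinom(n_genes * 2 * nrep, mu = mu, size = 1 / dispersion),
              n_genes, 2 * nrep,
              dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  count_table(m, rep(c("A", "B"), each = nrep))
}
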