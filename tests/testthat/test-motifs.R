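test_that("a sharp PWM scores its consensus at the maximum", {
  pw <- consensus_pwm("sharp", "ACGTA", p_major = 1 - 3e-12)
  seq <- paste0("TTTTT", "ACGTA", "TTTTT")
  hits <- scan_sequence(seq, pw, threshold_fraction = 0.999)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 5L)
  expect_equal(fwd$score, pwm_max_score(pw), tolerance = 1e-6)
  expect_equal(pwm_max_score(pw), 5 * log2(4), tolerance = 1e-9)
})

test_that("scanning the reverse complement mirrors hits exactly", {
  set.seed(71)
  for (i in 1:20) {
    seq <- random_dna(200)
    pw <- default_motif_set()[[sample.int(12, 1)]]
    h1 <- scan_sequence(seq, pw, 0.75)
    h2 <- scan_sequence(revcomp(seq), pw, 0.75)
    L <- pwm_length(pw)
    mirrored <- data.frame(offset = nchar(seq) - L - h1$offset,
                           strand = as.character(ifelse(h1$strand == "+", "-", "+")),
                           score = h1$score)
    o1 <- mirrored[order(mirrored$strand, mirrored$offset), ]
    o2 <- h2[order(h2$strand, h2$offset), c("offset", "strand", "score")]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
  }
})

test_that("scanner equals exhaustive brute force on random inputs", {
  set.seed(72)
  for (i in 1:25) {
    seq <- random_dna(sample(60:150, 1))
    if (i %% 5 == 0) {  # inject ambiguous bases
      pos <- sample.int(nchar(seq), 3)
      for (p in pos) substr(seq, p, p) <- "N"
    }
    pw <- default_motif_set()[[sample.int(12, 1)]]
    got <- scan_sequence(seq, pw, 0.8)
    got <- got[order(got$strand, got$offset), c("offset", "strand", "score")]
    rownames(got) <- NULL
    want <- scan_oracle(seq, pw, 0.8)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("scan threshold outside (0, 1] is rejected", {
  expect_error(scan_sequence("ACGTACGT", default_motif_set()[[1]], 0),
               "threshold_fraction")
  expect_error(scan_sequence("ACGTACGT", default_motif_set()[[1]], 1.1),
               "threshold_fraction")
})

test_that("background sampling is deterministic, sized and length-correct", {
  g <- c(chr1 = random_dna(5e4), chr2 = random_dna(3e4))
  bg <- sample_background(g, n = 500, length = 400, seed = 9)
  expect_length(bg, 500)
  expect_true(all(nchar(bg) == 400))
  expect_identical(sample_background(g, 500, 400, seed = 9), bg)
  expect_false(identical(sample_background(g, 500, 400, seed = 10), bg))
  expect_length(sample_background(g, 0, 400, seed = 1), 0)
  # windows never cross a chromosome boundary: every window is a slice
  idx <- sample.int(500, 20)
  ok <- vapply(idx, function(i) {
    any(vapply(names(g), function(ch) grepl(bg[[i]], g[[ch]], fixed = TRUE),
               logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("ambiguous-base windows are rejected from the background", {
  g <- c(chr1 = paste0(random_dna(2000), strrep("N", 3000), random_dna(2000)))
  bg <- sample_background(g, 50, 400, seed = 3, max_n_fraction = 0.1)
  fracN <- 1 - nchar(gsub("[^ACGT]", "", bg)) / nchar(bg)
  expect_true(all(fracN <= 0.1))
})

test_that("summit sequences are genome slices of the right width", {
  g <- c(chr1 = random_dna(10000))
  pk <- narrowpeak("chr1", c(4000, 100), c(4400, 500),
                   name = c("mid", "edge"), summit_offset = c(200L, 0L))
  seqs <- extract_summit_sequences(pk, g, flank = 200)
  expect_equal(unname(seqs["mid"]), substr(g[["chr1"]], 4001, 4400))
  expect_equal(nchar(seqs[["mid"]]), 400L)
  # summit at 100 -> left-truncated window of length 300, flagged
  expect_equal(nchar(seqs[["edge"]]), 300L)
  expect_true(attr(seqs, "truncated")[["edge"]])
  expect_false(attr(seqs, "truncated")[["mid"]])
  expect_error(extract_summit_sequences(narrowpeak("chrX", 0, 100), g),
               "unknown chromosome")
})

test_that("Fisher greater tail matches closed forms and the enumeration oracle", {
  expect_equal(fisher_exact_greater(rbind(c(2, 0), c(0, 2)))$p, 1 / 6)
  expect_equal(fisher_exact_greater(rbind(c(3, 1), c(1, 3)))$p, 17 / 70)
  expect_equal(fisher_exact_greater(rbind(c(0, 5), c(3, 2)))$p, 1)
  expect_error(fisher_exact_greater(rbind(c(-1, 1), c(1, 1))), "non-negative")
  or <- fisher_exact_greater(rbind(c(4, 0), c(0, 4)))$odds_ratio
  expect_equal(or, Inf)
  set.seed(73)
  for (i in 1:50) {
    tb <- matrix(sample(0:15, 4, TRUE), 2, 2)
    expect_equal(fisher_exact_greater(tb)$p,
                 fisher_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("single-motif enrichment detects a planted consensus", {
  set.seed(74)
  pw <- default_motif_set()[1:3]
  cons <- pwm_consensus(pw[[1]])
  peak <- vapply(1:200, function(i) {
    s <- random_dna(400)
    if (i <= 160) substr(s, 100, 100 + nchar(cons) - 1) <- cons
    s
  }, character(1))
  names(peak) <- sprintf("pk%03d", 1:200)
  bg <- stats::setNames(vapply(1:1000, function(i) random_dna(400),
                               character(1)), sprintf("bg%04d", 1:1000))
  res <- single_motif_enrichment(peak, bg, pw)
  top <- res[1, ]
  expect_equal(top$motif_id, pw[[1]]$motif_id)
  expect_lt(top$p, 1e-30)
  expect_gt(top$odds_ratio, 5)
})

test_that("a motif absent everywhere is unenriched", {
  pw <- list(consensus_pwm("absent", "ACGTACGTACGT", p_major = 0.97))
  peak <- stats::setNames(rep(strrep("A", 400), 5), paste0("p", 1:5))
  bg <- stats::setNames(rep(strrep("C", 400), 5), paste0("b", 1:5))
  res <- single_motif_enrichment(peak, bg, pw)
  expect_equal(res$p, 1)
  expect_equal(res$k_peak, 0L)
})

test_that("combination generation enumerates C(n, k) sorted tuples", {
  expect_length(generate_combinations(letters[1:3]), 1)
  combos <- generate_combinations(paste0("m", sprintf("%02d", 1:10)))
  expect_length(combos, 120)
  expect_true(all(vapply(combos, function(x) !is.unsorted(x), logical(1))))
  expect_false(anyDuplicated(vapply(combos, paste, character(1),
                                    collapse = "|")) > 0)
  expect_error(generate_combinations(c("a", "b"), 3), "at least 3")
})

test_that("combination span rule follows the window arithmetic", {
  ml <- c(m1 = 8L, m2 = 8L, m3 = 8L)
  mk <- function(offs) data.frame(motif_id = names(ml), offset = offs,
                                  stringsAsFactors = FALSE)
  expect_false(combination_present(mk(c(0, 300, 650)), names(ml), 500, ml))
  expect_true(combination_present(mk(c(0, 300, 450)), names(ml), 500, ml))
  # only two of three motifs present
  h2 <- mk(c(0, 10, 20))[1:2, ]
  expect_false(combination_present(h2, names(ml), 500, ml))
  expect_error(combination_present(mk(c(0, 1, 2)), c("m1", "m1", "m2"), 500, ml),
               "repeated")
  # any placement within a 400 bp sequence fits a 500 bp span
  expect_true(combination_present(mk(c(0, 200, 390)), names(ml), 500, ml))
})

test_that("with span >= sequence length the test reduces to co-presence", {
  set.seed(75)
  pw <- default_motif_set()[1:4]
  seqs <- stats::setNames(vapply(1:60, function(i) random_dna(400),
                                 character(1)), sprintf("s%03d", 1:60))
  bg <- stats::setNames(vapply(1:60, function(i) random_dna(400),
                               character(1)), sprintf("b%03d", 1:60))
  big <- combination_enrichment(seqs, bg, pw, span = 500)
  sc <- scan_sequences(seqs, pw)
  scb <- scan_sequences(bg, pw)
  combos <- generate_combinations(vapply(pw, function(p) p$motif_id,
                                         character(1)))
  for (j in seq_along(combos)) {
    kp <- sum(apply(sc$presence[, combos[[j]]], 1, all))
    kb <- sum(apply(scb$presence[, combos[[j]]], 1, all))
    row <- big[big$motif_1 == combos[[j]][1] & big$motif_2 == combos[[j]][2] &
                 big$motif_3 == combos[[j]][3], ]
    expect_equal(row$k_peak, kp)
    expect_equal(row$k_bg, kb)
  }
})

test_that("combination statistics are stable under motif-set growth", {
  set.seed(76)
  seqs <- stats::setNames(vapply(1:40, function(i) random_dna(400),
                                 character(1)), sprintf("s%03d", 1:40))
  bg <- stats::setNames(vapply(1:40, function(i) random_dna(400),
                               character(1)), sprintf("b%03d", 1:40))
  small <- combination_enrichment(seqs, bg, default_motif_set()[1:4])
  grown <- combination_enrichment(seqs, bg, default_motif_set()[1:6])
  key <- function(d) paste(d$motif_1, d$motif_2, d$motif_3)
  common <- intersect(key(small), key(grown))
  expect_length(common, 4)   # C(4,3)
  expect_equal(small$p[match(common, key(small))],
               grown$p[match(common, key(grown))])
  expect_equal(small$k_peak[match(common, key(small))],
               grown$k_peak[match(common, key(grown))])
})

test_that("an all-absent combination gets p = 1", {
  pw <- list(consensus_pwm("x1", "AAAACCCCGGGG", 0.97),
             consensus_pwm("x2", "CCCCGGGGTTTT", 0.97),
             consensus_pwm("x3", "GGGGTTTTAAAA", 0.97))
  seqs <- stats::setNames(rep(strrep("AT", 200), 4), paste0("s", 1:4))
  bg <- stats::setNames(rep(strrep("TA", 200), 4), paste0("b", 1:4))
  res <- combination_enrichment(seqs, bg, pw)
  expect_equal(res$k_peak, 0L)
  expect_equal(res$k_bg, 0L)
  expect_equal(res$p, 1)
})

test_that("GC-matched background tracks the target GC distribution", {
  set.seed(77)
  g <- c(chr1 = random_dna(2e5, gc = 0.5))
  gc_of <- function(s) nchar(gsub("[^GC]", "", s)) / nchar(s)
  # targets: the GC-richer half of windows drawn from the same genome
  cand <- sample_background(g, 400, 400, seed = 99)
  targets <- cand[gc_of(cand) > stats::median(gc_of(cand))]
  bg <- sample_background(g, 300, 400, seed = 5, match_gc_to = targets)
  plain <- sample_background(g, 300, 400, seed = 5)
  expect_length(bg, 300)
  expect_gt(mean(gc_of(bg)), mean(gc_of(plain)) + 0.005)
  expect_lt(abs(mean(gc_of(bg)) - mean(gc_of(targets))), 0.01)
})
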