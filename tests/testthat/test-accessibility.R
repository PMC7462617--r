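test_that("replicate merging unions overlapping intervals with support", {
  r1 <- narrowpeak("chr1", 100, 200, "a")
  r2 <- narrowpeak("chr1", 150, 300, "b")
  cons <- merge_replicate_peaks(list(r1, r2), min_support = 2)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 300L)
  expect_equal(cons$support, 2L)
  # identical replicates reproduce the set with full support
  cons3 <- merge_replicate_peaks(list(r1, r1, r1), min_support = 2)
  expect_equal(cons3[, c("start", "end")], r1[, c("start", "end")])
  expect_equal(cons3$support, 3L)
  expect_error(merge_replicate_peaks(list(r1), min_support = 2),
               "min_support")
})

test_that("min_support filters unreproducible peaks", {
  r1 <- narrowpeak("chr1", c(100, 1000), c(200, 1100))
  r2 <- narrowpeak("chr1", 120, 220)
  cons <- merge_replicate_peaks(list(r1, r2), min_support = 2)
  expect_equal(nrow(cons), 1L)   # the 1000-1100 singleton is dropped
  expect_equal(cons$end, 220L)
})

test_that("merging is idempotent on a consensus set", {
  set.seed(61)
  start <- sort(sample.int(1e6, 200))
  pk <- narrowpeak("chr1", start, start + 300)
  cons <- merge_replicate_peaks(list(pk), min_support = 1)
  again <- merge_replicate_peaks(list(cons), min_support = 1)
  expect_equal(again[, c("chrom", "start", "end")],
               cons[, c("chrom", "start", "end")])
})

test_that("consensus over jittered synthetic replicates recovers the loci", {
  cfg <- sim_config(seed = 62, n_peaks = 300, n_genes = 50,
                    chrom_lengths = c(chr1 = 2e6))
  ps <- generate_peak_sets(cfg)
  consA <- merge_replicate_peaks(ps$replicates$A, min_support = 2, "A")
  shared_or_A <- sum(ps$class_truth$class != "exclusive_B")
  expect_equal(nrow(consA), shared_or_A)
})

test_that("peak classification recovers planted classes exactly", {
  cfg <- sim_config(seed = 63, n_peaks = 500, n_genes = 50,
                    chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
                    frac_shared = 0.9, frac_exclusive_A = 0.05,
                    frac_exclusive_B = 0.05)
  ps <- generate_peak_sets(cfg)
  consA <- merge_replicate_peaks(ps$replicates$A, 2, "A")
  consB <- merge_replicate_peaks(ps$replicates$B, 2, "B")
  cl <- classify_peaks(consA, consB)
  expect_equal(sum(cl$counts), nrow(cl$peaks))       # conservation
  expect_equal(unname(cl$counts),
               c(450L, 25L, 25L))
  # per-peak classes match truth via locus overlap
  pooled_gr <- peaks_to_granges(cl$peaks)
  loci_gr <- peaks_to_granges(ps$loci)
  hits <- GenomicRanges::findOverlaps(pooled_gr, loci_gr)
  truth_class <- ps$class_truth$class[S4Vectors::subjectHits(hits)]
  expect_equal(cl$class[S4Vectors::queryHits(hits)], truth_class)
})

test_that("degenerate classifications behave", {
  a <- narrowpeak("chr1", c(0, 1000), c(400, 1400))
  cons <- merge_replicate_peaks(list(a), 1, "A")
  cl_same <- classify_peaks(cons, cons)
  expect_equal(unname(cl_same$fractions["shared"]), 1)
  b <- narrowpeak("chr1", 5000, 5400)
  consB <- merge_replicate_peaks(list(b), 1, "B")
  cl_disj <- classify_peaks(cons, consB)
  expect_equal(unname(cl_disj$fractions["shared"]), 0)
})

test_that("fragment-midpoint counting matches brute force", {
  set.seed(64)
  start <- seq(0, 99000, by = 1000)
  pooled <- narrowpeak("chr1", start, start + sample(200:600, 100, TRUE))
  frs <- lapply(1:4, function(j) {
    s <- sample.int(1e5, 2500)
    data.frame(chrom = "chr1", start = s, end = s + sample(50:150, 2500, TRUE))
  })
  names(frs) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  x <- count_reads_in_peaks(pooled, fragments = frs,
                            group = c("A", "A", "B", "B"))
  for (s in names(frs)) {
    mid <- (frs[[s]]$start + frs[[s]]$end) %/% 2
    brute <- vapply(seq_len(nrow(pooled)), function(i)
      sum(mid >= pooled$start[i] & mid < pooled$end[i]), numeric(1))
    expect_equal(unname(x$counts[, s]), brute)
  }
  # no fragments -> all-zero table; unknown chromosomes warn and are skipped
  empty <- lapply(frs, function(f) f[0, ])
  x0 <- count_reads_in_peaks(pooled, fragments = empty,
                             group = c("A", "A", "B", "B"))
  expect_true(all(x0$counts == 0))
  frs$A_r1$chrom[1] <- "chrUn"
  expect_warning(count_reads_in_peaks(pooled, fragments = frs,
                                      group = c("A", "A", "B", "B")),
                 "unknown chromosome")
})

test_that("precomputed locus counts transfer to pooled peaks", {
  loci <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                     start = c(100, 1000), end = c(500, 1400))
  m <- matrix(c(10, 20, 30, 40), 2, 2,
              dimnames = list(c("p1", "p2"), c("A_r1", "B_r1")))
  counts <- count_table(m, c("A", "B"))
  pooled <- narrowpeak("chr1", c(90, 980), c(510, 1410),
                       name = c("pool_1", "pool_2"))
  x <- count_reads_in_peaks(pooled, counts = counts, loci = loci)
  expect_equal(unname(x$counts), unname(m))
})

test_that("differential accessibility flags planted shifts and swaps sign", {
  cfg <- sim_config(seed = 65, n_peaks = 800, n_genes = 100,
                    chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
                    frac_shared = 0.9, frac_exclusive_A = 0.05,
                    frac_exclusive_B = 0.05, da_log2fc = 2,
                    coupled_fraction = 0, de_fraction = 0)
  ps <- generate_peak_sets(cfg)
  gn <- generate_genes(cfg, ps)
  cc <- generate_counts(cfg, list(class_truth = ps$class_truth,
                                  de_truth = gn$de_truth,
                                  expr_class = gn$expr_class))
  da <- differential_accessibility(cc$peak_counts)
  excl <- ps$class_truth$class != "shared"
  expect_gte(mean(da$significant[excl]), 0.8)
  fdp <- sum(da$significant & !excl) / max(1, sum(da$significant))
  expect_lte(fdp, 0.15)
  swapped <- count_table(cc$peak_counts$counts,
                         stats::setNames(ifelse(cc$peak_counts$group == "A",
                                                "B", "A"),
                                         names(cc$peak_counts$group)))
  sf <- size_factors_median_of_ratios(cc$peak_counts)
  da2 <- differential_accessibility(swapped, sf)
  expect_equal(da2$M, -da$M)
})

test_that("nearest-TSS annotation matches examples and brute force", {
  genes <- gene_table(c("g1", "g2"), "chr1", c(10000, 40000),
                      c(20000, 50000), c("+", "-"))
  # summit exactly at g1's TSS
  pk <- narrowpeak("chr1", 9800, 10200, "at_tss")
  ann <- annotate_peaks(pk, genes)
  expect_equal(ann$nearest_gene, "g1")
  expect_equal(ann$distance, 0L)
  expect_equal(ann$category, "tss_proximal")
  # nearest TSS just beyond the window is unassigned
  far <- narrowpeak("chr1", 210000, 210400, "far")  # summit 210200; g2 tss 49999
  ann2 <- annotate_peaks(far, genes, window = 150000)
  expect_true(is.na(ann2$nearest_gene))
  ann3 <- annotate_peaks(far, genes, window = 160201)
  expect_equal(ann3$nearest_gene, "g2")
  # random layouts equal the O(n*m) scan
  set.seed(66)
  for (rep in 1:5) {
    g <- gene_table(sprintf("g%03d", 1:100),
                    sample(c("chr1", "chr2"), 100, TRUE),
                    s <- sample.int(5e5, 100), s + sample(1000:5000, 100, TRUE),
                    sample(c("+", "-"), 100, TRUE))
    p0 <- sort(sample.int(5e5, 200))
    pks <- narrowpeak(sample(c("chr1", "chr2"), 200, TRUE), p0, p0 + 400)
    expect_equal(annotate_peaks(pks, g, window = 50000),
                 nearest_oracle(pks, g, window = 50000))
  }
})

test_that("annotation ties break toward the smaller gene id", {
  genes <- gene_table(c("gB", "gA"), "chr1", c(1000, 3000), c(2000, 4000),
                      c("+", "-"))
  # summit at 2499: gB tss 1000 (d 1499), gA tss 3999 (d 1500) -> gB
  # summit at 2500: d 1500 vs 1499 -> gA; equality case at 2499.5 impossible,
  # so construct exact tie: tss at 1000 and 4000
  g2 <- gene_table(c("gB", "gA"), "chr1", c(1000, 4000), c(2000, 5000),
                   c("+", "+"))
  pk <- narrowpeak("chr1", 2300, 2700, "tie")   # summit 2500, both d = 1500
  ann <- annotate_peaks(pk, g2)
  expect_equal(ann$nearest_gene, "gA")
})

test_that("TSS over-representation runs an exact one-sided test", {
  annA <- data.frame(category = rep(c("tss_proximal", "intergenic"), c(2, 0)))
  annB <- data.frame(category = rep(c("tss_proximal", "intergenic"), c(0, 2)))
  res <- tss_overrepresentation(annA, annB)
  expect_equal(res$p, 1 / 6)
  eqA <- data.frame(category = rep(c("tss_proximal", "genic"), c(10, 90)))
  eqB <- data.frame(category = rep(c("tss_proximal", "genic"), c(10, 90)))
  res2 <- tss_overrepresentation(eqA, eqB)
  expect_equal(res2$odds_ratio, 1)
})
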