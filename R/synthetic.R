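#' Built-in motif set for simulations
#'
#' Twelve PWMs with homeodomain/cardiac-factor style consensi (HOX-, PBX-,
#' MEIS-, GATA-, TEAD-, NKX-like plus generic fillers). Each motif has five
#' high-information positions and three degenerate positions, giving
#' per-window occurrence probabilities in the moderate range (roughly
#' 0.2-0.5 on 400 bp) so that co-occurrence tables are informative both for
#' planted-signal recovery and for null calibration.
#'
#' @return List of [pwm()] objects.
#' @export
default_motif_set <- function() {
  consensi <- c(HOX_like = "TAATTAGC", PBX_like = "TGATTGAT",
                MEIS_like = "TGACAGCT", GATA_like = "AGATAAGG",
                TEAD_like = "GGAATGTG", NKX_like = "TCAAGTGG",
                TF07 = "CCATATGG", TF08 = "GTCACGTG",
                TF09 = "AACCGGTT", TF10 = "TTGCGCAA",
                TF11 = "CAGCTGAC", TF12 = "GATCCGAT")
  strong <- c(1, 2, 4, 5, 7)   # high-information positions
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  lapply(names(consensi), function(id) {
    cons <- strsplit(consensi[[id]], "")[[1]]
    probs <- matrix(0, length(cons), 4)
    for (i in seq_along(cons)) {
      if (i %in% strong) {
        probs[i, ] <- 0.03
        probs[i, base_idx[cons[i]]] <- 0.91
      } else {
        probs[i, ] <- 0.2
        probs[i, base_idx[cons[i]]] <- 0.4
      }
    }
    pwm(id, probs, is_probs = TRUE)
  })
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-population dataset. The
#' defaults mirror the structure of a two-population FACS-sorted
#' progenitor study: 2 populations x 3 replicates, ~94%/3.5%/2.5%
#' shared/A-exclusive/B-exclusive peaks, negative binomial counts with
#' dispersion 0.1, planted log2 fold changes of 2, and a planted motif
#' triple in 60% of A-exclusive summit windows.
#'
#' @param seed global seed; all stage seeds derive from it via [child_seed()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gc_fraction genome GC content in (0,1).
#' @param n_genes,n_peaks numbers of genes and peak loci.
#' @param frac_shared,frac_exclusive_A,frac_exclusive_B peak class fractions
#'   (must sum to 1; realized counts follow the largest-remainder rule).
#' @param n_replicates replicates per population.
#' @param nb_mean_log2_range range of baseline log2 normalized means.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param de_fraction fraction of genes with a planted expression shift.
#' @param de_log2fc planted expression |log2 fold change| (A over B).
#' @param da_log2fc planted accessibility |log2 fold change| for exclusive peaks.
#' @param coupled_fraction fraction of exclusive peaks coupled to a planted
#'   concordant differentially expressed gene.
#' @param frac_specific_A,frac_specific_B fractions of genes expressed only
#'   in one population (silent in the other).
#' @param silent_log2_mean log2 normalized mean of a gene in the population
#'   where it is silent.
#' @param intergenic_mean NB mean of intergenic background windows.
#' @param n_intergenic_windows,intergenic_window_size intergenic background
#'   tiling (counts are emitted directly per window).
#' @param peak_width width of every true peak locus (bp).
#' @param jitter_frac per-replicate boundary jitter as a fraction of width.
#' @param libsize_range range of multiplicative library-size factors
#'   (drawn log-uniform).
#' @param motif_set list of [pwm()] objects.
#' @param planted_triple three motif ids planted jointly in A-exclusive
#'   summit windows.
#' @param planted_triple_rate fraction of A-exclusive windows carrying the
#'   planted triple.
#' @param planted_span bp window within which the three consensi are planted.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 3.2e6, chr2 = 3.2e6),
                       gc_fraction = 0.42,
                       n_genes = 1500L,
                       n_peaks = 2000L,
                       frac_shared = 0.94,
                       frac_exclusive_A = 0.035,
                       frac_exclusive_B = 0.025,
                       n_replicates = 3L,
                       nb_mean_log2_range = c(5, 9),
                       nb_dispersion = 0.1,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       da_log2fc = 2,
                       coupled_fraction = 0.3,
                       frac_specific_A = 0.15,
                       frac_specific_B = 0.05,
                       silent_log2_mean = 1,
                       intergenic_mean = 2,
                       n_intergenic_windows = 1000L,
                       intergenic_window_size = 5000L,
                       peak_width = 400L,
                       jitter_frac = 0.1,
                       libsize_range = c(0.5, 2),
                       motif_set = default_motif_set(),
                       planted_triple = NULL,
                       planted_triple_rate = 0.6,
                       planted_span = 300L) {
  ids <- vapply(motif_set, function(p) p$motif_id, character(1))
  if (is.null(planted_triple)) planted_triple <- ids[1:3]
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks), frac_shared = frac_shared,
              frac_exclusive_A = frac_exclusive_A,
              frac_exclusive_B = frac_exclusive_B,
              n_replicates = as.integer(n_replicates),
              nb_mean_log2_range = nb_mean_log2_range,
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_log2fc = de_log2fc, da_log2fc = da_log2fc,
              coupled_fraction = coupled_fraction,
              frac_specific_A = frac_specific_A,
              frac_specific_B = frac_specific_B,
              silent_log2_mean = silent_log2_mean,
              intergenic_mean = intergenic_mean,
              n_intergenic_windows = as.integer(n_intergenic_windows),
              intergenic_window_size = as.integer(intergenic_window_size),
              peak_width = as.integer(peak_width), jitter_frac = jitter_frac,
              libsize_range = libsize_range, motif_set = motif_set,
              planted_triple = planted_triple,
              planted_triple_rate = planted_triple_rate,
              planted_span = as.integer(planted_span))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(length(cfg$chrom_lengths) > 0 && !is.null(names(cfg$chrom_lengths)),
              "sim_config: chrom_lengths must be a named vector")
  assert_that(cfg$gc_fraction > 0 && cfg$gc_fraction < 1,
              "sim_config: gc_fraction must be in (0,1)")
  fs <- cfg$frac_shared + cfg$frac_exclusive_A + cfg$frac_exclusive_B
  assert_that(abs(fs - 1) < 1e-9,
              "sim_config: peak class fractions must sum to 1 (got %g)", fs)
  assert_that(cfg$nb_dispersion > 0, "sim_config: nb_dispersion must be > 0")
  assert_that(cfg$n_replicates >= 2, "sim_config: need >= 2 replicates")
  ids <- vapply(cfg$motif_set, function(p) p$motif_id, character(1))
  assert_that(all(cfg$planted_triple %in% ids),
              "sim_config: planted_triple not contained in motif_set")
  assert_that(length(unique(cfg$planted_triple)) == 3,
              "sim_config: planted_triple needs 3 distinct motif ids")
  maxcons <- max(vapply(cfg$motif_set, pwm_length, integer(1)))
  assert_that(cfg$planted_span >= 3 * maxcons,
              "sim_config: planted_span too small to fit 3 consensus sequences")
  assert_that(cfg$planted_span <= cfg$peak_width,
              "sim_config: planted_span exceeds the summit-window length")
  assert_that(cfg$planted_triple_rate >= 0 && cfg$planted_triple_rate <= 1,
              "sim_config: planted_triple_rate must be in [0,1]")
  invisible(cfg)
}

#' Largest-remainder apportionment
#'
#' Deterministically turns fractions into integer counts summing to `n`:
#' floor shares first, then one extra unit per largest fractional
#' remainder (ties resolved by position).
#'
#' @param n total count.
#' @param fracs numeric fractions summing to 1.
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, fracs) {
  assert_that(abs(sum(fracs) - 1) < 1e-9, "fractions must sum to 1")
  raw <- n * fracs
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

#' Generate an i.i.d. genome with fixed GC content
#'
#' @param config [sim_config()].
#' @return Named character vector of chromosome sequences; P(G) + P(C)
#'   equals `gc_fraction`, deterministic given `config$seed`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "genome"))
  gc <- config$gc_fraction
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(names(config$chrom_lengths), function(chrom) {
    n <- config$chrom_lengths[[chrom]]
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

# Disjoint slot layout shared by peak and gene placement. Each locus owns a
# slot of `slot_width` bp; its peak sits in the slot centre region and its
# gene TSS (when present) stays inside the same slot, so nearest-TSS
# assignment is unambiguous by construction.
slot_layout <- function(config) {
  slot <- max(5L * config$peak_width + 1000L, config$peak_width + 2600L)
  per_chrom <- pmax(0L, as.integer(floor(config$chrom_lengths / slot)))
  total <- sum(per_chrom)
  need <- config$n_peaks + max(0L, config$n_genes - config$n_peaks)
  assert_that(total >= need,
              "cannot place %d disjoint loci: only %d slots of %d bp available",
              need, total, slot)
  chroms <- rep(names(config$chrom_lengths), per_chrom)
  starts <- unlist(lapply(per_chrom, function(k) (seq_len(k) - 1L)))
  list(slot = slot, chrom = chroms, slot_start = starts * slot, n = total)
}

#' Generate replicate peak sets with known classes
#'
#' Places `n_peaks` disjoint true loci, assigns each a class by the
#' largest-remainder rule over the configured fractions, and emits
#' per-replicate narrowPeak tables: a shared locus appears in every
#' replicate of both populations, an exclusive locus only in its
#' population's replicates. Replicate boundaries are jittered by at most
#' `jitter_frac` of the width; the true summit (locus midpoint) is
#' recorded in each replicate's summit offset.
#'
#' @param config [sim_config()].
#' @param genome optional genome (used only to validate chromosome names).
#' @return List with `replicates` (list `A`/`B` of narrowPeak data frames),
#'   `loci` (true locus narrowPeak data frame), and `class_truth`
#'   (data frame peak_id, class).
#' @export
generate_peak_sets <- function(config, genome = NULL) {
  validate_sim_config(config)
  if (!is.null(genome)) {
    assert_that(all(names(config$chrom_lengths) %in% names(genome)),
                "genome is missing configured chromosomes")
  }
  set.seed(child_seed(config$seed, "peaks"))
  lay <- slot_layout(config)
  pick <- sort(sample.int(lay$n, config$n_peaks))
  w <- config$peak_width
  # peak start placed centrally so the gene slot region never collides
  off <- sample.int(lay$slot - w - 2400L, config$n_peaks, replace = TRUE) + 1200L
  loci <- narrowpeak(chrom = lay$chrom[pick],
                     start = lay$slot_start[pick] + off,
                     end = lay$slot_start[pick] + off + w,
                     name = sprintf("peak_%05d", seq_len(config$n_peaks)),
                     summit_offset = w %/% 2L)
  cls <- c("shared", "exclusive_A", "exclusive_B")
  counts <- largest_remainder(config$n_peaks,
                              c(config$frac_shared, config$frac_exclusive_A,
                                config$frac_exclusive_B))
  class_of <- sample(rep(cls, counts))
  jit <- max(1L, as.integer(round(config$jitter_frac * w)))
  make_rep <- function(pop, repl) {
    keep <- class_of == "shared" | class_of == paste0("exclusive_", pop)
    idx <- which(keep)
    js <- sample.int(2L * jit + 1L, length(idx), replace = TRUE) - jit - 1L
    je <- sample.int(2L * jit + 1L, length(idx), replace = TRUE) - jit - 1L
    start <- loci$start[idx] + js
    end <- loci$end[idx] + je
    summit <- peak_summit(loci)[idx]
    narrowpeak(chrom = loci$chrom[idx], start = start, end = end,
               name = sprintf("%s_rep%d_%s", pop, repl, loci$name[idx]),
               summit_offset = pmin(pmax(summit - start, 0L), end - start - 1L))
  }
  reps <- list(A = list(), B = list())
  for (pop in c("A", "B")) {
    for (r in seq_len(config$n_replicates)) {
      reps[[pop]][[paste0(pop, "_rep", r)]] <- make_rep(pop, r)
    }
  }
  list(replicates = reps, loci = loci,
       class_truth = data.frame(peak_id = loci$name, class = class_of,
                                stringsAsFactors = FALSE))
}

#' Generate gene models tied to peak loci
#'
#' Every gene TSS is placed 100-1000 bp from the summit of a distinct peak
#' locus (modelling promoter-proximal accessibility); surplus genes occupy
#' empty slots. Exclusive peaks designated as coupled receive a gene with a
#' planted concordant expression shift; remaining differential and
#' population-specific expression classes are assigned by largest
#' remainder among the unconstrained genes.
#'
#' @param config [sim_config()].
#' @param peaks result of [generate_peak_sets()].
#' @return List with `genes` (gene table), `de_truth`, `expr_class`,
#'   `coupling` truth data frames.
#' @export
generate_genes <- function(config, peaks) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "genes"))
  loci <- peaks$loci
  cls <- peaks$class_truth$class
  n_genes <- config$n_genes
  excl_A <- which(cls == "exclusive_A")
  excl_B <- which(cls == "exclusive_B")
  n_cA <- round(config$coupled_fraction * length(excl_A))
  n_cB <- round(config$coupled_fraction * length(excl_B))
  coupled_A <- if (n_cA > 0) sample(excl_A, n_cA) else integer(0)
  coupled_B <- if (n_cB > 0) sample(excl_B, n_cB) else integer(0)
  assert_that(n_genes >= n_cA + n_cB,
              "n_genes too small for the configured coupled fraction")
  # genes 1..n_owned sit in peak slots: coupled peaks first, then a random
  # subset of the remaining loci (random so that gene-less loci are spread
  # uniformly along the genome rather than clustered)
  other <- setdiff(seq_len(nrow(loci)), c(coupled_A, coupled_B))
  n_owned <- min(n_genes, nrow(loci))
  n_other <- n_owned - n_cA - n_cB
  assert_that(n_other >= 0, "n_genes too small for the coupled pairs")
  owner <- c(coupled_A, coupled_B,
             if (n_other > 0) sort(sample(other, n_other)) else integer(0))
  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  chrom <- character(n_genes)
  tss <- integer(n_genes)
  summit <- peak_summit(loci)
  d <- sample(100:1000, n_owned, replace = TRUE) *
    sample(c(-1L, 1L), n_owned, replace = TRUE)
  chrom[seq_len(n_owned)] <- loci$chrom[owner]
  tss[seq_len(n_owned)] <- summit[owner] + d
  if (n_genes > n_owned) {
    # surplus genes go to slots not used by peaks
    lay <- slot_layout(config)
    used <- paste(loci$chrom, loci$start %/% lay$slot)
    free <- which(!(paste(lay$chrom, lay$slot_start %/% lay$slot) %in% used))
    extra <- sample(free, n_genes - n_owned)
    chrom[(n_owned + 1):n_genes] <- lay$chrom[extra]
    tss[(n_owned + 1):n_genes] <- lay$slot_start[extra] +
      sample(1000:(lay$slot - 1000L), n_genes - n_owned, replace = TRUE)
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  len <- sample(2000:10000, n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  end <- ifelse(strand == "+", tss + len, tss + 1L)
  lim <- config$chrom_lengths[chrom]
  start <- pmax(0L, as.integer(start))
  end <- pmin(as.integer(lim), as.integer(end))
  genes <- gene_table(gene_id, chrom, start, end, strand)
  # expression classes and planted DE
  n_de <- round(config$de_fraction * n_genes)
  assert_that(n_de >= n_cA + n_cB,
              "de_fraction too small for the configured coupled fraction")
  idx_cA <- seq_len(n_cA)
  idx_cB <- n_cA + seq_len(n_cB)
  rest <- setdiff(seq_len(n_genes), c(idx_cA, idx_cB))
  de_extra <- if (n_de > n_cA + n_cB) sample(rest, n_de - n_cA - n_cB) else integer(0)
  de_lfc <- numeric(n_genes)
  de_lfc[idx_cA] <- config$de_log2fc
  de_lfc[idx_cB] <- -config$de_log2fc
  de_lfc[de_extra] <- sample(c(-1, 1), length(de_extra), replace = TRUE) *
    config$de_log2fc
  expr_class <- rep("shared", n_genes)
  pool <- setdiff(rest, de_extra)
  ns <- largest_remainder(n_genes, c(1 - config$frac_specific_A -
                                       config$frac_specific_B,
                                     config$frac_specific_A,
                                     config$frac_specific_B))
  nsA <- min(ns[2], length(pool))
  spA <- if (nsA > 0) sample(pool, nsA) else integer(0)
  pool2 <- setdiff(pool, spA)
  nsB <- min(ns[3], length(pool2))
  spB <- if (nsB > 0) sample(pool2, nsB) else integer(0)
  expr_class[spA] <- "specific_A"
  expr_class[spB] <- "specific_B"
  coupling <- data.frame(
    peak_id = loci$name[c(coupled_A, coupled_B)],
    gene_id = gene_id[c(idx_cA, idx_cB)],
    direction = rep(c("A", "B"), c(n_cA, n_cB)),
    stringsAsFactors = FALSE)
  list(genes = genes,
       de_truth = data.frame(gene_id = gene_id, log2fc = de_lfc,
                             stringsAsFactors = FALSE),
       expr_class = data.frame(gene_id = gene_id, class = expr_class,
                               stringsAsFactors = FALSE),
       coupling = coupling)
}

nb_draw <- function(mu_matrix, dispersion) {
  n <- length(mu_matrix)
  draws <- rnbinom(n, mu = as.numeric(mu_matrix), size = 1 / dispersion)
  matrix(draws, nrow(mu_matrix), ncol(mu_matrix), dimnames = dimnames(mu_matrix))
}

#' Generate NB count tables for genes, peaks and intergenic windows
#'
#' Counts follow `NB(mean = s_j * mu_f, dispersion)` with per-sample
#' library-size factors `s_j` drawn log-uniform over `libsize_range`.
#' Planted expression shifts split symmetrically across populations
#' (`mu * 2^(lfc/2)` in A, `mu * 2^(-lfc/2)` in B) so the base mean is
#' shift-invariant; population-specific genes are silent (fixed low mean)
#' in the other population; exclusive peaks carry the accessibility shift
#' `da_log2fc` with the matching sign.
#'
#' @param config [sim_config()].
#' @param truth list with `class_truth` (from [generate_peak_sets()]) and
#'   `de_truth`/`expr_class` (from [generate_genes()]).
#' @return List of three [count_table()]s: `gene_counts`, `peak_counts`,
#'   `intergenic_counts`, plus the drawn `size_factors` per assay.
#' @export
generate_counts <- function(config, truth) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "counts"))
  nrep <- config$n_replicates
  samples <- c(paste0("A_rep", seq_len(nrep)), paste0("B_rep", seq_len(nrep)))
  group <- stats::setNames(rep(c("A", "B"), each = nrep), samples)
  lsr <- log(config$libsize_range)
  sf_rna <- stats::setNames(exp(runif(2 * nrep, lsr[1], lsr[2])), samples)
  sf_atac <- stats::setNames(exp(runif(2 * nrep, lsr[1], lsr[2])), samples)

  # genes
  gid <- truth$de_truth$gene_id
  ng <- length(gid)
  base <- 2^runif(ng, config$nb_mean_log2_range[1], config$nb_mean_log2_range[2])
  lfc <- truth$de_truth$log2fc
  muA <- base * 2^(lfc / 2)
  muB <- base * 2^(-lfc / 2)
  silent <- 2^config$silent_log2_mean
  muA[truth$expr_class$class == "specific_B"] <- silent
  muB[truth$expr_class$class == "specific_A"] <- silent
  mu <- cbind(matrix(rep(muA, nrep), ng, nrep),
              matrix(rep(muB, nrep), ng, nrep))
  dimnames(mu) <- list(gid, samples)
  gene_counts <- count_table(nb_draw(sweep(mu, 2, sf_rna, "*"),
                                     config$nb_dispersion), group)

  # peaks
  pid <- truth$class_truth$peak_id
  np <- length(pid)
  pbase <- 2^runif(np, config$nb_mean_log2_range[1], config$nb_mean_log2_range[2])
  plfc <- ifelse(truth$class_truth$class == "exclusive_A", config$da_log2fc,
                 ifelse(truth$class_truth$class == "exclusive_B",
                        -config$da_log2fc, 0))
  pmu <- cbind(matrix(rep(pbase * 2^(plfc / 2), nrep), np, nrep),
               matrix(rep(pbase * 2^(-plfc / 2), nrep), np, nrep))
  dimnames(pmu) <- list(pid, samples)
  peak_counts <- count_table(nb_draw(sweep(pmu, 2, sf_atac, "*"),
                                     config$nb_dispersion), group)

  # intergenic windows (RNA assay, same samples/size factors)
  nw <- config$n_intergenic_windows
  wmu <- matrix(config$intergenic_mean, nw, 2 * nrep,
                dimnames = list(sprintf("window_%05d", seq_len(nw)), samples))
  intergenic_counts <- count_table(nb_draw(sweep(wmu, 2, sf_rna, "*"),
                                           config$nb_dispersion), group)

  list(gene_counts = gene_counts, peak_counts = peak_counts,
       intergenic_counts = intergenic_counts,
       size_factors = list(rna = sf_rna, atac = sf_atac))
}

#' Plant a motif triple into A-exclusive summit windows
#'
#' For a `planted_triple_rate` fraction of A-exclusive peak loci, writes
#' the consensus sequence of each of the three configured motifs (random
#' strand each) at non-overlapping offsets that all fall within
#' `planted_span` bp inside the 400 bp summit window. The genome is
#' mutated in place; planted positions are recorded relative to the summit
#' window start.
#'
#' @param config [sim_config()].
#' @param genome named character vector (mutated copy is returned).
#' @param peaks result of [generate_peak_sets()].
#' @param flank summit window half-width (bp).
#' @return List with `genome` (mutated) and `planted` (data frame
#'   seq_id, motif_id, offset, strand).
#' @export
plant_motif_triples <- function(config, genome, peaks, flank = 200L) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, "plant"))
  ids <- vapply(config$motif_set, function(p) p$motif_id, character(1))
  triple <- config$motif_set[match(config$planted_triple, ids)]
  cons <- vapply(triple, pwm_consensus, character(1))
  idx_A <- which(peaks$class_truth$class == "exclusive_A")
  n_plant <- round(config$planted_triple_rate * length(idx_A))
  planted <- data.frame(seq_id = character(0), motif_id = character(0),
                        offset = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  if (n_plant == 0) return(list(genome = genome, planted = planted))
  chosen <- sort(sample(idx_A, n_plant))
  summit <- peak_summit(peaks$loci)[chosen]
  win_len <- 2L * flank
  span <- config$planted_span
  third <- span %/% 3L
  assert_that(third >= max(nchar(cons)),
              "planted_span too small to fit 3 consensus sequences")
  rows <- vector("list", n_plant)
  for (k in seq_len(n_plant)) {
    chrom <- peaks$loci$chrom[chosen[k]]
    win_start <- summit[k] - flank          # 0-based genome offset
    span_off <- sample.int(win_len - span + 1L, 1L) - 1L
    offs <- integer(3)
    strands <- character(3)
    for (m in 1:3) {
      L <- nchar(cons[m])
      offs[m] <- span_off + (m - 1L) * third +
        sample.int(third - L + 1L, 1L) - 1L
      strands[m] <- sample(c("+", "-"), 1L)
      s <- if (strands[m] == "+") cons[m] else revcomp(cons[m])
      abs0 <- win_start + offs[m]           # 0-based
      substr(genome[[chrom]], abs0 + 1L, abs0 + L) <- s
    }
    rows[[k]] <- data.frame(seq_id = peaks$loci$name[chosen[k]],
                            motif_id = vapply(triple, function(p) p$motif_id,
                                              character(1)),
                            offset = offs, strand = strands,
                            stringsAsFactors = FALSE)
  }
  list(genome = genome, planted = do.call(rbind, rows))
}

#' Simulate a complete two-population dataset
#'
#' Runs every generator stage in order (genome, peak sets, genes, counts,
#' motif planting) and optionally writes the dataset directory:
#' `genome.fa`, `genes.tsv`, `{A,B}_rep{i}.narrowPeak`, `gene_counts.tsv`,
#' `peak_counts.tsv`, `intergenic_counts.tsv`, `motifs.pfm`,
#' `peak_loci.tsv`, `truth/*.tsv` and a `config.yaml` echo. Byte-identical
#' under a fixed seed.
#'
#' @param config [sim_config()].
#' @param dir output directory (created); NULL to keep everything in memory.
#' @return List with all generated objects and truth tables.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  validate_sim_config(config)
  genome <- generate_genome(config)
  peaks <- generate_peak_sets(config, genome)
  genes <- generate_genes(config, peaks)
  counts <- generate_counts(config, list(class_truth = peaks$class_truth,
                                         de_truth = genes$de_truth,
                                         expr_class = genes$expr_class))
  pl <- plant_motif_triples(config, genome, peaks)
  ds <- list(config = config, genome = pl$genome,
             replicates = peaks$replicates, peak_loci = peaks$loci,
             genes = genes$genes,
             gene_counts = counts$gene_counts,
             peak_counts = counts$peak_counts,
             intergenic_counts = counts$intergenic_counts,
             size_factors = counts$size_factors,
             truth = list(peak_class = peaks$class_truth,
                          de = genes$de_truth,
                          expr_class = genes$expr_class,
                          coupling = genes$coupling,
                          planted = pl$planted))
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a simulated dataset to a directory
#' @param ds result of [simulate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_genome(ds$genome, file.path(dir, "genome.fa"))
  write_gene_table(ds$genes, file.path(dir, "genes.tsv"))
  for (pop in names(ds$replicates)) {
    for (nm in names(ds$replicates[[pop]])) {
      write_narrowpeak(ds$replicates[[pop]][[nm]],
                       file.path(dir, paste0(nm, ".narrowPeak")))
    }
  }
  write_count_table(ds$gene_counts, file.path(dir, "gene_counts.tsv"), "gene_id")
  write_count_table(ds$peak_counts, file.path(dir, "peak_counts.tsv"), "peak_id")
  write_count_table(ds$intergenic_counts, file.path(dir, "intergenic_counts.tsv"),
                    "window_id")
  write_pfm(ds$config$motif_set, file.path(dir, "motifs.pfm"))
  write.table(data.frame(peak_id = ds$peak_loci$name, chrom = ds$peak_loci$chrom,
                         start = ds$peak_loci$start, end = ds$peak_loci$end,
                         summit = peak_summit(ds$peak_loci)),
              file.path(dir, "peak_loci.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(ds$truth)) {
    write.table(ds$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- ds$config
  cfg$motif_set <- vapply(cfg$motif_set, function(p) p$motif_id, character(1))
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
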