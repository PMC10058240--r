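# PWM construction, exact-p scanning, grouping, non-overlap counting, LREs.

test_that("PWM construction follows the pseudocount arithmetic", {
  counts <- matrix(c(3, 1, 0, 0), ncol = 1)
  pwm <- pwm_from_counts(counts, pseudocount = 1, id = "t")
  expect_equal(unname(pwm$probs[, 1]), c(0.5, 0.25, 0.125, 0.125))
  # columns always sum to 1
  set.seed(2)
  cm <- matrix(rpois(4 * 8, 4), nrow = 4)
  p2 <- pwm_from_counts(cm, pseudocount = 0.5)
  expect_equal(unname(colSums(p2$probs)), rep(1, 8))
  # single-base columns with zero pseudocount give probability-1 columns
  p3 <- pwm_from_counts(matrix(c(5, 0, 0, 0), ncol = 1), pseudocount = 0)
  expect_equal(unname(p3$probs[, 1]), c(1, 0, 0, 0))
  expect_error(pwm_from_counts(matrix(0, 4, 1), pseudocount = 0), "zero")
})

test_that("scan p-values equal exhaustive enumeration", {
  # the canonical single-sequence case
  acgt <- pwm_from_counts(diag(4), pseudocount = 0, id = "acgt")
  h <- scan_sequence(acgt, "ACGT", p_threshold = 1, both_strands = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(h$p, 0.25^4)
  # random PWMs of width 5 against the brute-force oracle
  set.seed(5)
  for (i in 1:5) {
    cm <- matrix(rpois(4 * 5, 3) + 1, nrow = 4)
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    pwm <- pwm_from_counts(cm, pseudocount = 1, background = bg, id = "r")
    oracle <- oracle_pwm_pvalues(pwm)
    seq_i <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    hits <- scan_sequence(pwm, seq_i, p_threshold = 1, both_strands = FALSE)
    for (j in seq_len(nrow(hits))) {
      expect_lt(abs(hits$p[j] - oracle(hits$score[j])), 1e-9)
    }
  }
})

test_that("scanning respects strands, N windows and the threshold", {
  lib <- default_motif_library()
  gbox <- lib$pwms$Gbox_bZIP
  cons <- pwm_consensus(gbox)
  seq_i <- paste0("AATT", cons, "AANTT",
                  as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons))),
                  "GGAA")
  hits <- scan_sequence(gbox, seq_i, p_threshold = 1e-4, both_strands = TRUE)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$start[hits$strand == "+"][1], 5L)
  # monotonicity: a lower threshold never yields more hits
  h_loose <- scan_sequence(gbox, seq_i, p_threshold = 1e-3)
  h_tight <- scan_sequence(gbox, seq_i, p_threshold = 1e-6)
  expect_lte(nrow(h_tight), nrow(h_loose))
  # sequences shorter than the motif yield no hits
  expect_equal(nrow(scan_sequence(gbox, "ACG")), 0)
  # palindromic motif: forward and reverse hits reported separately
  pal <- pwm_from_counts({
    m <- matrix(1, 4, 6)
    cod <- etiofoot:::.base_codes("CACGTG")
    m[cbind(cod + 1, 1:6)] <- 50
    m
  }, pseudocount = 0, id = "pal")
  hp <- scan_sequence(pal, "TTCACGTGTT", p_threshold = 1e-3)
  expect_equal(sort(hp$strand), c("+", "-"))
  expect_equal(unique(hp$start), 3L)
})

test_that("reverse-complementing the sequence preserves per-group counts", {
  d <- small_scenario_data()
  seq_f <- substr(as.character(d$genome_a[[1]]), 50001, 60000)
  seq_r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_f)))
  count_by_motif <- function(s) {
    h <- do.call(rbind, lapply(d$pwms, scan_sequence, sequence = s, p_threshold = 1e-4))
    table(factor(h$motif_id, levels = names(d$pwms)))
  }
  expect_equal(count_by_motif(seq_f), count_by_motif(seq_r))
})

test_that("non-overlap counting is greedy by p, order-independent", {
  hits <- data.frame(motif_id = c("m1", "m2", "m2"),
                     start = c(1, 5, 21), end = c(8, 12, 27),
                     p = c(1e-5, 1e-4, 1e-4), group = "G")
  expect_equal(unname(count_nonoverlapping(hits, scope = "per-group")["G"]), 2L)
  expect_length(count_nonoverlapping(hits[0, ], scope = "per-group"), 0)
  expect_equal(unname(count_nonoverlapping(hits[1, ], scope = "per-group")["G"]), 1L)
  # per-motif scope keeps overlaps across different motifs
  expect_equal(sum(count_nonoverlapping(hits, scope = "per-motif")), 3L)
  # permutation invariance given the tie-breaks
  set.seed(8)
  big <- data.frame(motif_id = sample(c("a", "b"), 40, TRUE),
                    start = sample.int(200, 40, TRUE))
  big$end <- big$start + 7L
  big$p <- sample(c(1e-5, 1e-4, 1e-3), 40, TRUE)
  big$group <- "G"
  ref <- count_nonoverlapping(big, scope = "per-group")
  for (i in 1:5) {
    perm <- big[sample.int(nrow(big)), ]
    expect_equal(count_nonoverlapping(perm, scope = "per-group"), ref)
  }
})

test_that("group assignment labels unmapped motifs and LRE windows count correctly", {
  map <- data.frame(motif_id = c("m1", "m2"), group = c("G-box", "G-box"))
  hits <- data.frame(motif_id = c("m1", "m2", "m3"), start = 1:3, end = 8:10,
                     p = 1e-5)
  expect_warning(out <- assign_groups(hits, map), "ungrouped")
  expect_equal(out$group, c("G-box", "G-box", "ungrouped"))
  # LRE census window: [TSS - 1500, CDS end] in gene orientation
  gene <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 5000,
                     cds_start = 5100, cds_end = 7000)
  fam <- data.frame(motif_id = c("m1", "m2"), group = c("G-box", "I-box"))
  h <- data.frame(motif_id = c("m1", "m1", "m1", "m2"), chrom = "chr1",
                  start = c(3500, 3502, 2000, 6990), end = c(3507, 3509, 2007, 6997),
                  p = c(1e-6, 1e-5, 1e-6, 1e-6))
  counts <- count_lres(gene, h, fam)
  expect_equal(unname(counts["G-box"]), 1L)  # overlap collapsed, outside excluded
  expect_equal(unname(counts["I-box"]), 1L)
  # minus-strand gene reflects the window
  gene_m <- data.frame(gene_id = "g", chrom = "chr1", strand = "-", tss = 7000,
                       cds_start = 5000, cds_end = 6900)
  h2 <- data.frame(motif_id = "m1", chrom = "chr1", start = 8400, end = 8407, p = 1e-6)
  expect_equal(unname(count_lres(gene_m, h2, fam)["G-box"]), 1L)
  h3 <- data.frame(motif_id = "m1", chrom = "chr1", start = 8600, end = 8607, p = 1e-6)
  expect_equal(unname(count_lres(gene_m, h3, fam)["G-box"]), 0L)
})

test_that("PWM clustering groups identical motifs and separates distinct ones", {
  lib <- default_motif_library()
  two <- list(lib$pwms$Gbox_bZIP, lib$pwms$AP2_ERF)
  cl2 <- cluster_pwms(two, similarity_threshold = 0.8)
  expect_equal(length(unique(cl2$group)), 2)
  dup <- list(lib$pwms$Gbox_bZIP,
              {p <- lib$pwms$Gbox_bZIP; p$id <- "copy"; p})
  cl1 <- cluster_pwms(dup, similarity_threshold = 0.8)
  expect_equal(length(unique(cl1$group)), 1)
  # duplicating a whole library leaves the number of groups unchanged
  four <- c(two, lapply(two, function(p) { p$id <- paste0(p$id, "_b"); p }))
  cl4 <- cluster_pwms(four, similarity_threshold = 0.8)
  expect_equal(length(unique(cl4$group)), 2)
})

test_that("MEME and group-map round trips preserve the library", {
  lib <- default_motif_library()
  mp <- tempfile(fileext = ".meme")
  write_meme(lib$pwms, mp)
  back <- read_meme(mp)
  expect_identical(names(back), names(lib$pwms))
  for (id in names(back)) {
    expect_equal(back[[id]]$probs, lib$pwms[[id]]$probs, tolerance = 1e-4)
    expect_equal(back[[id]]$background, lib$pwms[[id]]$background, tolerance = 1e-5)
  }
  gp <- tempfile(fileext = ".tsv")
  write_group_map(lib$group_map, gp)
  expect_equal(read_group_map(gp), lib$group_map)
})
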