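# Binomial footprint statistic, hexamer bias, FLR mixture, filtering.

test_that("binomial scores match the direct-summation oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample.int(200, 1)
    k <- sample.int(n + 1, 1) - 1L
    p <- runif(1, 0.05, 0.95)
    expect_lt(abs(etiofoot:::.log10_binom_tail(k, n, p) -
                    oracle_log10_binom_tail(k, n, p)), 1e-10)
  }
})

test_that("footprint detection scores the constructed depletion correctly", {
  # shoulder 10, width 10: 50 forward cuts in the left shoulder, none in
  # the window; reverse mirrored.  p = 0.5^50 per strand.
  n <- 200L
  fwd <- rep(0L, n); rev <- rep(0L, n)
  s <- 100L; w <- 10L; sh <- 10L
  fwd[(s - sh):(s - 1)] <- 5L          # 50 cuts left shoulder
  rev[(s + w):(s + w + sh - 1)] <- 5L  # 50 cuts right shoulder
  prof <- make_profile(fwd, rev)
  dhs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60, 160))
  fp <- detect_footprints(prof, dhs, widths = w, shoulder = sh,
                          score_threshold = -10)
  expect_gte(length(fp), 1)
  best <- fp[which.min(fp$score)]
  expect_equal(IRanges::start(best), s)
  expect_equal(unname(best$score), 2 * 50 * log10(0.5), tolerance = 1e-9)
  # threshold keeps -12.3-class candidates and rejects -8.1-class ones
  expect_true(all(fp$score < -10))
  # uniform cuts: nothing detected
  set.seed(1)
  uni <- make_profile(rpois(n, 5), rpois(n, 5))
  expect_length(detect_footprints(uni, dhs, widths = w, shoulder = sh), 0)
})

test_that("footprint score is invariant under strand swap plus mirroring", {
  set.seed(11)
  n <- 400L
  fwd <- rpois(n, 4); rev <- rpois(n, 4)
  fwd[180:200] <- 0L; rev[180:200] <- 0L
  # mirror-symmetric search interval: [100, 301] maps onto itself
  dhs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 301))
  fp1 <- detect_footprints(make_profile(fwd, rev), dhs, score_threshold = -2)
  # mirror the coordinates and swap the strands
  fp2 <- detect_footprints(make_profile(base::rev(rev), base::rev(fwd)), dhs,
                           score_threshold = -2)
  expect_equal(sort(fp1$score), sort(fp2$score), tolerance = 1e-12)
  expect_equal(sort(n + 1 - IRanges::end(fp2)), sort(IRanges::start(fp1)))
})

test_that("hexamer bias estimation recovers planted rates", {
  set.seed(3)
  L <- 3e5
  seqs <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  # uniform cutting -> all rates about 1
  unif <- make_profile(rpois(L, 2), rpois(L, 2), treatment = "deproteinated")
  b0 <- estimate_hexamer_bias(unif, genome)
  expect_equal(mean(b0$rate), 1, tolerance = 1e-9)
  expect_lt(stats::sd(b0$rate), 0.1)
  # planted 4x rate for one hexamer
  planted <- setNames(rep(1, 4096), etiofoot:::.kmer_strings(6))
  planted["AAAAAA"] <- 4
  bw <- etiofoot:::.bias_weights(planted, seqs)
  set.seed(4)
  ctrl <- make_profile(rpois(L, 2 * bw$fwd), rpois(L, 2 * bw$rev),
                       treatment = "deproteinated")
  b1 <- estimate_hexamer_bias(ctrl, genome)
  expect_lt(abs(b1$rate["AAAAAA"] / stats::median(b1$rate) - 4) / 4, 0.1)
  # guards
  expect_error(estimate_hexamer_bias(make_profile(1:5), genome), "deproteinated")
  short <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_equal(length(estimate_hexamer_bias(
    make_profile(rep(1L, 4), rep(1L, 4), treatment = "deproteinated"),
    short)$absent), 4096)
})

test_that("expected cut proportions normalise bias weights over a region", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50), collapse = "")))
  ones <- setNames(rep(1, 4096), etiofoot:::.kmer_strings(6))
  r <- expected_cut_rates(ones, genome, GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)))
  expect_equal(r, rep(0.01, 100))
  expect_equal(sum(r), 1)
  # N-context bases carry weight 1 before normalisation
  gn <- Biostrings::DNAStringSet(c(chr1 = paste0(paste(rep("ACGT", 10), collapse = ""),
                                                 "NNNNNNNNNN",
                                                 paste(rep("ACGT", 10), collapse = ""))))
  rn <- expected_cut_rates(ones, gn, GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 50)))
  expect_equal(rn, rep(0.1, 10))
})

test_that("the FLR mixture separates protection from cutting bias", {
  # parameter recovery on simulated depletion statistics
  set.seed(21)
  x <- c(rnorm(600, -1.5, 0.3), rnorm(1400, 0, 0.3))
  fit <- etiofoot:::.fit_flr_mixture(x)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$mu[1] + 1.5), 0.1)
  expect_lt(abs(fit$mu[2]), 0.1)
  expect_lt(abs(fit$pi[1] - 0.3), 0.05)
  expect_equal(sum(fit$pi), 1)
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(fit$loglik) > -1e-8))
  # independent cross-check: an established mixture fitter agrees
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.vector(mc$parameters$mean)),
               tolerance = 0.05)
  # bias-trap decoys (x ~ 0) get negative FLR on the synthetic scenario
  d <- small_scenario_data()
  pk <- call_peaks(d$profiles[["0"]])
  fp <- detect_footprints(d$profiles[["0"]], pk)
  bias <- estimate_hexamer_bias(d$control, d$genome_a)
  fl <- footprint_flr(fp, d$profiles[["0"]], bias, d$genome_a)
  is_decoy <- IRanges::overlapsAny(fl$footprints, d$truth_a$decoys)
  is_true <- IRanges::overlapsAny(fl$footprints, d$truth_a$footprints)
  expect_gt(mean(fl$footprints$flr[is_decoy] < 0), 0.8)
  expect_gt(mean(fl$footprints$flr[is_true] >= 0), 0.9)
  expect_error(footprint_flr(fp[1:5], d$profiles[["0"]], bias, d$genome_a), "20")
})

test_that("FLR filtering and extension follow their contracts", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101:110 * 10, 101:110 * 10 + 15),
                               flr = c(rep(-1, 3), rep(2, 7)), time = 0,
                               seqlengths = c(chr1 = 10000))
  out <- filter_footprints(gr)
  expect_length(out$retained, 7)
  expect_equal(out$report$reduction, 0.3)
  # all FLR >= 0 is the identity
  all_pos <- gr; all_pos$flr <- abs(all_pos$flr)
  expect_length(filter_footprints(all_pos)$retained, length(gr))
  # empty input
  empty <- filter_footprints(GenomicRanges::GRanges())
  expect_length(empty$retained, 0)
  expect_equal(nrow(empty$report), 0)
  # extension pads and clips without merging
  fp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 2, 130), c(120, 10, 140)),
                               seqlengths = c(chr1 = 10000))
  ext <- extend_footprints(fp, 4)
  expect_equal(IRanges::start(ext), c(96, 1, 126))
  expect_equal(IRanges::end(ext), c(124, 14, 144))
  expect_length(ext, 3)  # overlapping records are not merged
})
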