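# Peak calling, DHS set algebra, SPOT, TSS profiles, feature annotation.

test_that("peak caller finds planted blocks and ignores flat profiles", {
  set.seed(1)
  n <- 20000L
  flat <- rpois(n, 2)
  expect_length(call_peaks(make_profile(flat), fold_threshold = 5), 0)
  expect_length(call_peaks(make_profile(rep(0L, n))), 0)
  # one 400-bp block at 10x background
  x <- rpois(n, 1)
  x[10001:10400] <- rpois(400, 10)
  pk <- call_peaks(make_profile(x, rep(0L, n)), window = 101, fold_threshold = 5,
                   min_width = 100)
  expect_length(pk, 1)
  expect_lt(abs(IRanges::start(pk) - 10001), 51)
  expect_lt(abs(IRanges::end(pk) - 10400), 51)
  # two blocks separated by more than merge_gap stay separate
  y <- rpois(n, 1)
  y[2001:2400] <- rpois(400, 10)
  y[5001:5400] <- rpois(400, 10)
  expect_length(call_peaks(make_profile(y, rep(0L, n)), merge_gap = 100), 2)
})

test_that("DHS classification matches the per-base occupancy oracle", {
  tp <- c("0", "0.5", "2", "4", "24")
  # definitional cases
  same <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 200), c(50, 300)))
  cls <- classify_dhs_sets(setNames(rep(list(same), 5), tp))
  expect_equal(cls$hyperconserved, GenomicRanges::reduce(same))
  expect_length(cls$light_specific, 0)
  only_light <- setNames(c(list(GenomicRanges::GRanges()),
                           rep(list(same), 4)), tp)
  cls2 <- classify_dhs_sets(only_light)
  expect_length(cls2$hyperconserved, 0)
  expect_equal(cls2$light_specific, GenomicRanges::reduce(same))
  expect_error(classify_dhs_sets(only_light[1:4]), "five")
  # randomised property: equality with brute force, disjointness
  set.seed(42)
  for (rep_i in 1:25) {
    colls <- setNames(lapply(1:5, function(i)
      random_granges(sample.int(50, 1), 10000L)), tp)
    got <- classify_dhs_sets(colls)
    want <- oracle_dhs_sets(colls, 10000L)
    expect_equal(IRanges::ranges(got$hyperconserved), IRanges::ranges(want$hyperconserved))
    expect_equal(IRanges::ranges(got$light_specific), IRanges::ranges(want$light_specific))
    expect_length(GenomicRanges::intersect(got$hyperconserved, got$light_specific), 0)
  }
})

test_that("SPOT score is the in-peak cut fraction", {
  x <- rep(0L, 1000); x[100:199] <- 1L  # 100 cuts
  prof <- make_profile(x, rep(0L, 1000))
  all_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 250))
  expect_equal(spot_score(prof, all_in), 1.0)
  part <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 179))  # 80 of 100
  expect_equal(spot_score(prof, part), 0.8)
  expect_equal(spot_score(prof, GenomicRanges::GRanges()), 0)
  expect_error(spot_score(make_profile(rep(0L, 10)), all_in), "zero")
  # monotone as peaks grow
  expect_gte(spot_score(prof, all_in), spot_score(prof, part))
})

test_that("TSS profiles reflect strand, normalisation and planted gains", {
  # single plus-strand gene: depth profile equals its normalised counts
  n <- 10000L
  x <- rpois(n, 2)
  prof <- make_profile(x, rep(0L, n))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 5000L, end = 6000L, tss = 5000L,
                      cds_start = 5100L, cds_end = 5900L, has_utr3 = TRUE)
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5100, 5900),
                                 strand = "+", type = "CDS", gene_id = "g1")
  ann <- gene_annotation(genes, feat, c(chr1 = n))
  tp <- tss_profile(prof, ann, "depth")
  expect_length(tp$values, 4001)
  scale <- 1e6 / prof$library_size
  expect_equal(tp$values, x[3000:7000] * scale)
  # log ratio of a profile against itself is exactly zero
  lr <- tss_profile(prof, ann, "logratio", profile_b = prof)
  expect_true(all(lr$values == 0))
  # planted upstream gain shows up in the synthetic scenario
  d <- small_scenario_data()
  lr2 <- tss_profile(d$profiles[["2"]], d$annotation_a, "logratio",
                     profile_b = d$profiles[["0"]])
  up <- lr2$offsets >= -500 & lr2$offsets < 0
  far <- lr2$offsets >= 500 & lr2$offsets <= 2000
  expect_gt(mean(lr2$values[up]), 0)
  expect_lt(abs(mean(lr2$values[far])), 0.1)
})

test_that("nearest TSS distances are signed by gene orientation", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "+"), start = c(100L, 400L),
                      end = c(300L, 600L), tss = c(100L, 400L),
                      cds_start = c(120L, 420L), cds_end = c(280L, 580L),
                      has_utr3 = TRUE)
  ann <- gene_annotation(genes, GenomicRanges::GRanges(), c(chr1 = 1000L))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(150, 100, 40), c(150, 100, 40)))
  d <- nearest_tss_distances(iv, ann)
  expect_equal(d[1], 50)    # downstream of the + strand TSS at 100
  expect_equal(d[2], 0)     # exactly at a TSS
  expect_equal(d[3], -60)   # upstream of the + strand TSS at 100
  # minus-strand gene: upstream is the high-coordinate side
  genes_m <- transform(genes[1, ], strand = "-", tss = 300L)
  ann_m <- gene_annotation(genes_m, GenomicRanges::GRanges(), c(chr1 = 1000L))
  dm <- nearest_tss_distances(GenomicRanges::GRanges("chr1", IRanges::IRanges(250, 250)),
                              ann_m)
  expect_equal(dm, 50)      # 50 bases 3' (downstream) of the - strand TSS
  dm2 <- nearest_tss_distances(GenomicRanges::GRanges("chr1", IRanges::IRanges(350, 350)),
                               ann_m)
  expect_equal(dm2, -50)    # 50 bases 5' (upstream) of the - strand TSS
})

test_that("feature annotation applies midpoint precedence and densities scale", {
  d <- small_scenario_data()
  ann <- d$annotation_a
  g <- ann$genes[ann$genes$strand == "+", ][1, ]
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(g$tss - 1000, g$tss + 450, 5),   # promoter, intron-ish, intergenic
    c(g$tss - 990, g$tss + 460, 15)))
  counts <- annotate_features(iv, ann)
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts["promoter"]), 1L)
  expect_equal(unname(counts["intergenic"]), 1L)
  # promoter takes precedence over any overlapping feature
  assignment <- attr(counts, "assignment")
  expect_equal(assignment[1], "promoter")
  dens <- feature_density(counts, ann)
  expect_true(all(is.finite(dens[counts > 0])))
  # densities: 10 intervals in 1000 bp of intron -> 0.01 per base
  intr <- etiofoot:::.features_of_type(ann, "intron")
  intron_len <- sum(IRanges::width(intr))
  k <- 10L
  mids <- IRanges::start(intr)[1] + 10 + seq_len(k)
  ivs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mids, mids))
  cts <- annotate_features(ivs, ann)
  dens2 <- feature_density(cts, ann)
  expect_equal(unname(dens2["intron"]), k / intron_len)
})

test_that("locus fold change is a guarded ratio of normalised means", {
  n <- 2000L
  a <- rep(3L, n); b <- rep(1L, n)
  p24 <- make_profile(a, rep(0L, n)); p0 <- make_profile(b, rep(0L, n))
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1001), c(1000, 2000)))
  # identical profiles give 1
  fc_id <- locus_fold_change(p24, p24, loci)
  expect_equal(fc_id$fold_change, c(1, 1))
  # cpm normalisation makes the constant-rate ratio 1 as well; use eps = 0
  # on raw-equal libraries scaled so the means differ 3x
  p0b <- make_profile(b * 3L, rep(0L, n))  # same library size as p24
  fc <- locus_fold_change(p24, p0b, loci, eps = 0)
  expect_equal(fc$fold_change, c(1, 1))
  # equal libraries, locus means 3 vs 1 -> fold change 3
  c0 <- c(rep(1L, 1000), rep(5L, 1000))
  p0c <- make_profile(c0, rep(0L, n))
  fc3 <- locus_fold_change(p24, p0c, loci, eps = 0)
  expect_equal(fc3$fold_change, c(3, 3 / 5))
  # zero dark coverage is flagged as eps-dominated but finite
  z <- rep(0L, n); z[1:1000] <- 5L
  pz <- make_profile(z, rep(0L, n))
  fcz <- locus_fold_change(pz, pz, GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1600)),
                           eps = 0.1)
  expect_true(is.finite(fcz$fold_change))
  expect_true(fcz$eps_dominated)
  expect_error(locus_fold_change(p24, p0, GenomicRanges::GRanges()), "empty")
})
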