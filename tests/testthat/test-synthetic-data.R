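# Synthetic-data generator: determinism, forced composition, planted truth.

test_that("scenario validation rejects impossible designs", {
  expect_error(synthetic_scenario(gc_fraction = 1.5), "gc_fraction")
  expect_error(synthetic_scenario(footprint_protection = -0.1), "footprint_protection")
  expect_error(synthetic_scenario(time_points = c(0, 2, 1)), "increasing")
  expect_error(synthetic_scenario(n_replicates = 0), "replicate")
  expect_error(
    generate_genome_and_annotation(
      synthetic_scenario(genome_length = 5e4, n_genes = 40,
                         n_footprints = 10, n_decoys = 0)),
    "too short")
})

test_that("genome generation is deterministic and honours composition", {
  sc <- synthetic_scenario(seed = 5, genome_length = 1.2e5, n_genes = 8,
                           n_footprints = 10, n_decoys = 4, gc_fraction = 1.0)
  g1 <- generate_genome_and_annotation(sc, "A")
  g2 <- generate_genome_and_annotation(sc, "A")
  expect_identical(as.character(g1$genome[[1]]), as.character(g2$genome[[1]]))
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  freq <- Biostrings::alphabetFrequency(g1$genome)[1, c("A", "C", "G", "T")]
  expect_equal(sum(freq[c("A", "T")]), 0)
  # byte-identical files under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1$genome, f1); write_genome_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- tempfile(); a2 <- tempfile()
  suppressWarnings(write_annotation_gff3(g1$annotation, a1))
  suppressWarnings(write_annotation_gff3(g2$annotation, a2))
  expect_identical(readLines(a1), readLines(a2))
})

test_that("the configured fraction of gene models lacks a 3'UTR", {
  sc <- synthetic_scenario(seed = 2, genome_length = 4e5, n_genes = 30,
                           n_footprints = 30, n_decoys = 10, frac_no_utr3 = 0.3)
  ga <- generate_genome_and_annotation(sc, "A")
  expect_equal(sum(!ga$annotation$genes$has_utr3), round(0.3 * 30))
  # and the GFF3 reflects it
  p <- tempfile(fileext = ".gff3")
  suppressWarnings(write_annotation_gff3(ga$annotation, p))
  a2 <- read_annotation_gff3(p)
  expect_equal(sum(!a2$genes$has_utr3), round(0.3 * 30))
})

test_that("motif planting writes consensus sequences at truth positions", {
  d <- small_scenario_data()
  inst <- d$truth_a$instances
  cons <- vapply(d$pwms, pwm_consensus, character(1))
  seq_chr <- as.character(d$genome_a[[1]])
  idx <- seq_len(min(25, nrow(inst)))
  for (i in idx) {
    written <- substr(seq_chr, inst$start[i], inst$end[i])
    expected <- if (inst$strand[i] == "+") cons[[inst$motif_id[i]]] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cons[[inst$motif_id[i]]])))
    expect_identical(written, expected)
  }
  # group map closure: every planted motif resolves to a group label
  gm <- d$group_map
  expect_true(all(inst$motif_id %in% gm$motif_id))
  expect_true(all(d$truth_a$footprints$motif_id %in% gm$motif_id))
})

test_that("C4-like promoters of species A carry the designed LRE excess", {
  d <- small_scenario_data()
  ratio <- d$scenario$species_pair_design$lre_ratio
  lre_a <- subset(d$truth_a$instances, role == "lre")
  lre_b <- subset(d$truth_b$instances, role == "lre")
  per_gene_a <- table(lre_a$gene_id)
  per_gene_b <- table(lre_b$gene_id)
  expect_true(all(per_gene_a == ratio * per_gene_b[1]))
  expect_equal(nrow(lre_a), ratio * nrow(lre_b))
  # planted footprints always lie inside a planted accessible region
  expect_true(all(IRanges::overlapsAny(d$truth_a$footprints, d$truth_a$dhs)))
})

test_that("cut simulation matches its Poisson design", {
  # flat accessibility, no bias, no footprints: genome-wide mean ~ depth
  sc <- synthetic_scenario(seed = 9, genome_length = 1e6, n_genes = 10,
                           n_footprints = 10, n_decoys = 0,
                           peak_depth = 10, background_fraction = 1,
                           bias_profile = setNames(rep(1, 4096),
                                                   etiofoot:::.kmer_strings(6)))
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 1e6, replace = TRUE), collapse = "")))
  empty_truth <- list(dhs = NULL, genes = NULL, footprints = NULL, occupancy = NULL)
  cuts <- simulate_cut_profiles(sc, genome, empty_truth)
  expect_named(cuts$profiles, c("0", "0.5", "2", "4", "24"))
  m <- mean(total_cuts(cuts$profiles[["0"]], "chr1"))
  expect_lt(abs(m - 10) / 10, 0.05)
  # conservation: summed control cuts equal the library size
  expect_equal(sum(total_cuts(cuts$control, "chr1")), cuts$control$library_size)
})

test_that("full protection (phi = 0) silences cuts inside occupied footprints", {
  sc <- synthetic_scenario(seed = 10, genome_length = 2e5, n_genes = 12,
                           n_footprints = 20, n_decoys = 0,
                           footprint_protection = 0, peak_depth = 30)
  ga <- generate_genome_and_annotation(sc, "A")
  la <- generate_motif_landscape(sc, ga$genome, ga$annotation, ga$truth)
  cuts <- simulate_cut_profiles(sc, la$genome, la$truth)
  x <- total_cuts(cuts$profiles[["0"]], "chr1")
  fp <- la$truth$footprints
  inside <- unlist(lapply(seq_along(fp), function(i)
    IRanges::start(fp)[i]:IRanges::end(fp)[i]))
  flank <- unique(unlist(lapply(seq_along(fp), function(i)
    c(IRanges::start(fp)[i] - (30:1), IRanges::end(fp)[i] + (1:30)))))
  flank <- setdiff(flank, inside)
  expect_lt(mean(x[inside]) / mean(x[flank]), 0.05)
})

test_that("expression simulation recovers its design", {
  sc <- synthetic_scenario(seed = 3, genome_length = 6e5, n_genes = 40,
                           n_footprints = 40, n_decoys = 10)
  ga <- generate_genome_and_annotation(sc, "A")
  gb <- generate_genome_and_annotation(sc, "B")
  ex <- simulate_expression(sc, ga$annotation, gb$annotation)
  v <- ex$expr_a$values
  meta <- ex$expr_a$meta
  # flat genes move only by sampling noise at decent depth
  flat <- ex$truth$orthogroup[ex$truth$class == "flat" & ex$truth$base_mean >= 100]
  flat_genes <- ex$ortholog_map$gene_a[match(flat, ex$ortholog_map$orthogroup)]
  tp_means <- sapply(sort(unique(meta$time)), function(t)
    rowMeans(v[flat_genes, meta$time == t, drop = FALSE]))
  ratio <- apply(tp_means, 1, function(r) max(r) / min(r))
  expect_true(median(ratio) < 1.5)
  # designed 4x (A) vs 2x (B) induction: ratio-of-ratios ~ 2 on raw counts
  c4 <- ex$truth$orthogroup[ex$truth$class == "c4" & ex$truth$base_mean >= 100]
  ga_ids <- ex$ortholog_map$gene_a[match(c4, ex$ortholog_map$orthogroup)]
  gb_ids <- ex$ortholog_map$gene_b[match(c4, ex$ortholog_map$orthogroup)]
  vb <- ex$expr_b$values
  rr <- vapply(seq_along(ga_ids), function(i) {
    fa <- mean(v[ga_ids[i], meta$time == 24]) / mean(v[ga_ids[i], meta$time == 0])
    fb <- mean(vb[gb_ids[i], meta$time == 24]) / mean(vb[gb_ids[i], meta$time == 0])
    fa / fb
  }, numeric(1))
  expect_lt(abs(mean(rr) - 2) / 2, 0.2)
  expect_error(simulate_expression(synthetic_scenario(n_replicates = 0), ga$annotation),
               "replicate")
})
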