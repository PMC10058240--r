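#' Call accessibility peaks from a cut profile
#'
#' Simplified stand-in peak caller: both strands are pooled, the per-base
#' rate is smoothed with a centred running window, and maximal runs where
#' the windowed rate reaches `fold_threshold` times the global genome-wide
#' rate are reported, merged when separated by at most `merge_gap` bases
#' and filtered to a minimum width.  The downstream set algebra accepts
#' externally produced peak sets (e.g. narrowPeak) just as well.
#'
#' @param profile A `CutProfile`.
#' @param window Smoothing window width in bases (odd values are used as
#'   given; even values are incremented).
#' @param fold_threshold Windowed rate must exceed this multiple of the
#'   global rate (> 1).
#' @param merge_gap Merge runs separated by at most this many bases.
#' @param min_width Discard merged peaks narrower than this.
#' @return `GRanges` of peaks, sorted and non-overlapping (a
#'   `DHSCollection`); empty for an all-zero profile.
#' @export
call_peaks <- function(profile, window = 101L, fold_threshold = 5,
                       merge_gap = 100L, min_width = 100L) {
  .assert(fold_threshold > 1, "fold_threshold must exceed 1")
  if (window %% 2L == 0L) window <- window + 1L
  hw <- (window - 1L) %/% 2L
  total <- sum(vapply(names(profile$fwd), function(ch) sum(total_cuts(profile, ch)),
                      numeric(1)))
  glen <- sum(profile$seqlengths)
  if (total == 0) {
    return(GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  seqlengths = profile$seqlengths))
  }
  global_rate <- total / glen
  out <- list()
  for (ch in names(profile$fwd)) {
    x <- as.numeric(total_cuts(profile, ch))
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - hw, 1L)
    hi <- pmin(seq_len(n) + hw, n)
    rate <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    mask <- rate >= fold_threshold * global_rate
    r <- rle(mask)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(s[keep], e[keep]),
                                          seqlengths = profile$seqlengths)
    }
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  seqlengths = profile$seqlengths))
  }
  gr <- GenomicRanges::reduce(do.call(c, unname(out)), min.gapwidth = merge_gap + 1L)
  gr[IRanges::width(gr) >= min_width]
}

#' Classify DHSs into hyperconserved and light-specific sets
#'
#' Per-base set algebra over the five time-point collections:
#' hyperconserved positions are covered at every time point;
#' light-specific positions are covered at all four light time points but
#' not in the dark (0 h) sample.  Both outputs are merged, sorted,
#' non-overlapping interval sets, and are disjoint by construction.
#'
#' @param collections Named list of exactly five `GRanges`, names being
#'   the time points in hours; the smallest label is the dark sample.
#' @return List with `hyperconserved` and `light_specific` `GRanges`.
#' @export
classify_dhs_sets <- function(collections) {
  .assert(length(collections) == 5 && !is.null(names(collections)),
          "exactly five labelled time-point collections are required")
  times <- suppressWarnings(as.numeric(names(collections)))
  .assert(!anyNA(times), "collection names must be numeric time labels")
  ord <- order(times)
  collections <- lapply(collections[ord], GenomicRanges::reduce)
  dark <- collections[[1]]
  light <- collections[-1]
  hyper <- Reduce(GenomicRanges::intersect, collections)
  light_all <- Reduce(GenomicRanges::intersect, light)
  light_specific <- GenomicRanges::setdiff(light_all, dark)
  list(hyperconserved = hyper, light_specific = light_specific)
}

#' SPOT score: fraction of cuts falling inside peaks
#'
#' @param profile A `CutProfile`.
#' @param peaks `GRanges` of peaks (overlaps are merged before counting).
#' @return Proportion in `[0, 1]`.
#' @export
spot_score <- function(profile, peaks) {
  total <- profile$library_size
  .assert(total > 0, "SPOT score undefined for a profile with zero cuts")
  if (!length(peaks)) return(0)
  peaks <- GenomicRanges::reduce(peaks)
  inside <- 0
  for (ch in unique(as.character(GenomeInfoDb::seqnames(peaks)))) {
    if (!ch %in% names(profile$fwd)) next
    x <- total_cuts(profile, ch)
    p <- peaks[as.character(GenomeInfoDb::seqnames(peaks)) == ch]
    s <- pmax(IRanges::start(p), 1L)
    e <- pmin(IRanges::end(p), length(x))
    for (i in seq_along(p)) inside <- inside + sum(x[s[i]:e[i]])
  }
  inside / total
}

#' TSS-centred accessibility profile
#'
#' Averages depth-normalised cut counts (cuts per million per base, both
#' strands pooled) over a window of `flank` bases either side of every
#' eligible TSS; minus-strand genes are reflected so negative offsets are
#' always upstream.  In `logratio` mode the per-base log2 ratio of two
#' normalised profiles (light vs dark) is averaged instead, with a
#' pseudocount of `eps` counts added to both before the ratio.
#'
#' @param profile_a A `CutProfile` (the only profile in `depth` mode; the
#'   numerator in `logratio` mode).
#' @param annotation A `GeneAnnotation`.
#' @param mode `"depth"` or `"logratio"`.
#' @param profile_b Denominator profile, required for `logratio`.
#' @param flank Half-window in bases (default 2000).
#' @param eps Pseudocount in raw count units for the log ratio.
#' @return Object of class `TSSProfile`: list with `offsets`
#'   (`-flank:flank`), `values` (per-offset mean), `n_genes`, `mode`.
#' @export
tss_profile <- function(profile_a, annotation, mode = c("depth", "logratio"),
                        profile_b = NULL, flank = 2000L, eps = 0.5) {
  mode <- match.arg(mode)
  if (mode == "logratio") .assert(!is.null(profile_b), "logratio mode needs profile_b")
  g <- annotation$genes
  elig <- g$tss - flank >= 1 & g$tss + flank <= annotation$seqlengths[g$chrom]
  .assert(any(elig), "no gene lies fully inside the chromosome with the requested flank")
  g <- g[elig, , drop = FALSE]
  cpm_a <- cut_cpm(profile_a)
  if (mode == "logratio") {
    cpm_b <- cut_cpm(profile_b)
    eps_a <- eps * cpm_a$scale
    eps_b <- eps * cpm_b$scale
  }
  acc <- numeric(2L * flank + 1L)
  for (i in seq_len(nrow(g))) {
    idx <- (g$tss[i] - flank):(g$tss[i] + flank)
    va <- cpm_a$total[[g$chrom[i]]][idx]
    v <- if (mode == "depth") va else {
      vb <- cpm_b$total[[g$chrom[i]]][idx]
      log2((va + eps_a) / (vb + eps_b))
    }
    if (g$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  structure(list(offsets = seq.int(-flank, flank), values = acc / nrow(g),
                 n_genes = nrow(g), mode = mode), class = "TSSProfile")
}

#' @export
print.TSSProfile <- function(x, ...) {
  cat(sprintf("TSSProfile (%s): %d offsets over %d genes\n",
              x$mode, length(x$offsets), x$n_genes))
  invisible(x)
}

#' Signed distance from interval midpoints to the nearest TSS
#'
#' The distance runs from the interval midpoint (ties at even widths
#' resolved toward the lower coordinate) to the closest TSS, negative
#' when the midpoint lies upstream (5') of that TSS in the orientation of
#' the TSS's gene.  Equidistant TSSs are resolved toward the lower
#' coordinate.
#'
#' @param intervals `GRanges`.
#' @param annotation A `GeneAnnotation` (non-empty).
#' @return Integer vector of signed distances, one per interval.
#' @export
nearest_tss_distances <- function(intervals, annotation) {
  g <- annotation$genes
  .assert(nrow(g) > 0, "annotation has no genes")
  mids <- (IRanges::start(intervals) + IRanges::end(intervals)) %/% 2L
  chroms <- as.character(GenomeInfoDb::seqnames(intervals))
  out <- integer(length(intervals))
  for (ch in unique(chroms)) {
    gi <- which(g$chrom == ch)
    .assert(length(gi) > 0, sprintf("no annotated gene on chromosome %s", ch))
    o <- order(g$tss[gi], g$gene_id[gi])
    tss <- g$tss[gi][o]; strand <- g$strand[gi][o]
    ii <- which(chroms == ch)
    pos <- findInterval(mids[ii], tss)
    for (k in seq_along(ii)) {
      m <- mids[ii[k]]
      cand <- unique(pmin(pmax(c(pos[k], pos[k] + 1L), 1L), length(tss)))
      dd <- abs(m - tss[cand])
      best <- cand[which.min(dd)]   # which.min keeps the first (lower-coordinate) tie
      out[ii[k]] <- if (strand[best] == "+") m - tss[best] else tss[best] - m
    }
  }
  out
}

.FEATURE_ORDER <- c("promoter", "five_prime_UTR", "CDS", "intron",
                    "three_prime_UTR", "intergenic")

#' Assign intervals to genomic feature categories
#'
#' Each interval is assigned exactly one category by the position of its
#' midpoint, under the precedence promoter > 5'UTR > CDS > intron >
#' 3'UTR > intergenic.
#'
#' @param intervals `GRanges`.
#' @param annotation A `GeneAnnotation`.
#' @param promoter_width Promoter extent upstream of the TSS (default
#'   2000).
#' @return Named integer vector of counts over the six categories
#'   (summing to `length(intervals)`), with the per-interval assignment
#'   in attribute `"assignment"`.
#' @export
annotate_features <- function(intervals, annotation, promoter_width = 2000L) {
  mids <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(intervals),
    IRanges::IRanges((IRanges::start(intervals) + IRanges::end(intervals)) %/% 2L,
                     width = 1L))
  sets <- list(
    promoter = promoter_ranges(annotation, promoter_width),
    five_prime_UTR = .features_of_type(annotation, "five_prime_UTR"),
    CDS = .features_of_type(annotation, "CDS"),
    intron = .features_of_type(annotation, "intron"),
    three_prime_UTR = .features_of_type(annotation, "three_prime_UTR"))
  assignment <- rep("intergenic", length(intervals))
  for (f in rev(names(sets))) {
    hit <- IRanges::overlapsAny(mids, sets[[f]], ignore.strand = TRUE)
    assignment[hit] <- f
  }
  counts <- setNames(integer(length(.FEATURE_ORDER)), .FEATURE_ORDER)
  tab <- table(assignment)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "assignment") <- assignment
  counts
}

#' Per-feature interval density
#'
#' Divides each feature's interval count by the total genomic length of
#' that feature class (summed over all instances, without merging, so
#' duplicated annotations scale counts and lengths together).
#'
#' @param feature_counts Named counts as from [annotate_features()].
#' @param annotation A `GeneAnnotation`.
#' @param promoter_width Promoter extent used for the counts.
#' @return Named numeric of densities (count per base); features with
#'   zero total length get `NA` with a warning.
#' @export
feature_density <- function(feature_counts, annotation, promoter_width = 2000L) {
  lens <- c(
    promoter = sum(IRanges::width(promoter_ranges(annotation, promoter_width))),
    five_prime_UTR = sum(IRanges::width(.features_of_type(annotation, "five_prime_UTR"))),
    CDS = sum(IRanges::width(.features_of_type(annotation, "CDS"))),
    intron = sum(IRanges::width(.features_of_type(annotation, "intron"))),
    three_prime_UTR = sum(IRanges::width(.features_of_type(annotation, "three_prime_UTR"))))
  covered <- GenomicRanges::reduce(c(
    GenomicRanges::GRanges(annotation$genes$chrom,
                           IRanges::IRanges(annotation$genes$start, annotation$genes$end)),
    GenomicRanges::granges(promoter_ranges(annotation, promoter_width))),
    ignore.strand = TRUE)
  lens["intergenic"] <- sum(annotation$seqlengths) - sum(IRanges::width(covered))
  feats <- names(feature_counts)
  dens <- as.numeric(feature_counts) / as.numeric(lens[feats])
  names(dens) <- feats
  if (any(lens[feats] == 0 & feature_counts > 0)) {
    warning("feature class with zero total length; density undefined (NA)")
  }
  dens[lens[feats] == 0] <- NA_real_
  dens
}

#' Locus-level accessibility fold change (light vs dark)
#'
#' Mean depth-normalised cut density of each locus in the 24-h profile
#' divided by the 0-h profile, with a pseudocount `eps` (in cuts per
#' million per base) added to both means.
#'
#' @param profile_24h,profile_0h `CutProfile`s.
#' @param loci Non-empty `GRanges`.
#' @param eps Pseudocount added to numerator and denominator means.
#' @return `data.frame` with `mean_24h`, `mean_0h`, `fold_change`, and
#'   `eps_dominated` (`TRUE` when the dark mean is below `eps`).
#' @export
locus_fold_change <- function(profile_24h, profile_0h, loci, eps = 0.1) {
  .assert(length(loci) > 0, "empty locus list")
  cpm24 <- cut_cpm(profile_24h)$total
  cpm0 <- cut_cpm(profile_0h)$total
  m24 <- numeric(length(loci)); m0 <- numeric(length(loci))
  chs <- as.character(GenomeInfoDb::seqnames(loci))
  for (i in seq_along(loci)) {
    idx <- IRanges::start(loci)[i]:IRanges::end(loci)[i]
    m24[i] <- mean(cpm24[[chs[i]]][idx])
    m0[i] <- mean(cpm0[[chs[i]]][idx])
  }
  data.frame(mean_24h = m24, mean_0h = m0,
             fold_change = (m24 + eps) / (m0 + eps),
             eps_dominated = m0 < eps)
}

#' Write / read a DHS collection as BED
#' @param peaks `GRanges`.
#' @param path BED file path.
#' @return Invisibly `path`; the reader returns a `GRanges`.
#' @export
write_peaks_bed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}
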