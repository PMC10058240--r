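#' Add pseudo-3'UTRs to genes lacking one
#'
#' Gene models without an annotated 3'UTR gain one of exactly `length`
#' bases immediately beyond the stop codon in gene orientation (clipped
#' at chromosome ends, with a message when clipping occurs); genes with a
#' 3'UTR are untouched.  The default of 339 bp is the mean length of
#' annotated 3'UTRs in the leafy Cleome genome this convention was
#' developed for.
#'
#' @param annotation A `GeneAnnotation`.
#' @param length Pseudo-UTR length in bases (> 0).
#' @return A new `GeneAnnotation` with added `three_prime_UTR` features
#'   and updated gene bounds.
#' @export
extend_pseudo_utr <- function(annotation, length = 339L) {
  .assert(length > 0, "extension length must be positive")
  g <- annotation$genes
  feats <- annotation$features
  add <- list()
  for (i in which(!g$has_utr3)) {
    sl <- annotation$seqlengths[g$chrom[i]]
    if (g$strand[i] == "+") {
      s <- g$cds_end[i] + 1L
      e <- min(s + length - 1L, sl)
    } else {
      e <- g$cds_start[i] - 1L
      s <- max(e - length + 1L, 1L)
    }
    if (e < s) next
    if (e - s + 1L < length) {
      message(sprintf("pseudo-3'UTR of %s clipped to %d bp at chromosome end",
                      g$gene_id[i], e - s + 1L))
    }
    add[[base::length(add) + 1L]] <- data.frame(chrom = g$chrom[i], start = s, end = e,
                                                strand = g$strand[i], gene_id = g$gene_id[i])
    g$start[i] <- min(g$start[i], s)
    g$end[i] <- max(g$end[i], e)
    if (g$strand[i] == "+") g$tss[i] <- g$start[i] else g$tss[i] <- g$end[i]
    g$has_utr3[i] <- TRUE
  }
  if (base::length(add)) {
    df <- do.call(rbind, add)
    new_feats <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                        strand = df$strand, type = "three_prime_UTR",
                                        gene_id = df$gene_id)
    GenomeInfoDb::seqlevels(new_feats) <- GenomeInfoDb::seqlevels(feats)
    feats <- c(feats, new_feats)
  }
  gene_annotation(g, feats, annotation$seqlengths)
}

.values_of <- function(x) if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)

.rewrap <- function(x, values) {
  if (inherits(x, "ExpressionMatrix")) expression_matrix(values, x$meta) else values
}

#' Quantile-normalise expression columns
#'
#' After normalisation every sample column has the identical sorted value
#' vector (the across-sample mean of order statistics); ties within a
#' column receive the mean of the order-statistic means they span.
#' Delegates to `limma::normalizeQuantiles`.
#'
#' @param x Numeric matrix or `ExpressionMatrix` (>= 2 samples).
#' @return Same shape as the input.
#' @export
quantile_normalize <- function(x) {
  v <- .values_of(x)
  .assert(ncol(v) >= 2, "quantile normalisation needs at least 2 samples")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  .rewrap(x, out)
}

#' Scale each sample to mean 1
#'
#' Divides every column by its mean, so a value of 1 represents the
#' average transcript abundance of that sample; this puts samples of
#' different depth (and different species) on a shared relative scale.
#'
#' @param x Numeric matrix or `ExpressionMatrix`; all column means must
#'   be positive.
#' @return Same shape as the input, all column means exactly 1.
#' @export
sample_mean_scale <- function(x) {
  v <- .values_of(x)
  mns <- colMeans(v)
  .assert(all(mns > 0), "every sample must have a positive mean")
  .rewrap(x, sweep(v, 2, mns, "/"))
}

#' Row-mean log transform for expression heatmaps
#'
#' `log10(value / row mean)`, with zeros floored at `floor` times the row
#' mean before the ratio.
#'
#' @param x Numeric matrix or `ExpressionMatrix`; all row means must be
#'   positive.
#' @param floor Relative floor applied to zero values (default 0, i.e.
#'   zeros give `-Inf`).
#' @return Same shape as the input.
#' @export
row_mean_log_transform <- function(x, floor = 0) {
  v <- .values_of(x)
  rm <- rowMeans(v)
  .assert(all(rm > 0), "every row must have a positive mean")
  ratio <- v / rm
  if (floor > 0) ratio[ratio < floor] <- floor
  .rewrap(x, log10(ratio))
}

#' Row z-scores
#'
#' Per row subtracts the mean and divides by the sample standard
#' deviation; constant rows map to all-zero and are flagged in attribute
#' `"constant_rows"`.
#'
#' @param x Numeric matrix or `ExpressionMatrix` (>= 2 samples).
#' @return Same shape as the input.
#' @export
zscore_rows <- function(x) {
  v <- .values_of(x)
  .assert(ncol(v) >= 2, "z-scores need at least 2 samples")
  rm <- rowMeans(v)
  rs <- apply(v, 1, stats::sd)
  const <- rs == 0
  rs[const] <- 1
  out <- (v - rm) / rs
  out[const, ] <- 0
  res <- .rewrap(x, out)
  attr(res, "constant_rows") <- rownames(v)[const] %||% which(const)
  res
}

#' Differentially expressed genes by two-method intersection
#'
#' The robust DEG set is the intersection of two independent calls on the
#' same contrast, after a low-expression filter:
#' * method A: exact conditional Poisson test (`poisson.test`) on
#'   replicate-summed counts of the two conditions;
#' * method B: Welch t-test on log2(count + 1) across replicates, applied
#'   within the method's candidate set -- genes whose mean log fold change
#'   passes the `min_fold` floor.
#' P-values are Benjamini-Hochberg adjusted within each method (for
#' method B, among its fold-floor candidates); a gene is robust when both
#' adjusted p-values fall below `alpha`.  Genes outside method B's
#' candidate set have `padj_b = NA` and are never robust.
#'
#' @param x `ExpressionMatrix` of counts.
#' @param contrast Two time-point labels `c(t_ref, t_alt)` (consecutive
#'   points of the course).
#' @param alpha Per-method significance level after adjustment.
#' @param min_fold Fold-change floor for method B (>= 1).
#' @param min_mean_count Low-expression filter: genes with mean count
#'   below this across all samples are dropped before testing.
#' @return Object of class `DEResult`: `data.frame` with `gene_id`,
#'   `log2_fc`, `p_a`, `p_b`, `padj_a`, `padj_b`, `call_a`, `call_b`,
#'   `robust`.
#' @export
detect_de_genes <- function(x, contrast, alpha = 0.05, min_fold = 1.5,
                            min_mean_count = 5) {
  .assert(inherits(x, "ExpressionMatrix"), "x must be an ExpressionMatrix of counts")
  .assert(length(contrast) == 2, "contrast must name two time points")
  i1 <- which(x$meta$time == contrast[1])
  i2 <- which(x$meta$time == contrast[2])
  .assert(length(i1) > 0 && length(i2) > 0, "contrast time points absent from metadata")
  if (length(i1) < 2 || length(i2) < 2) {
    stop("method B needs >= 2 replicates per condition; robust set undefined",
         call. = FALSE)
  }
  v <- x$values
  keep <- rowMeans(v) >= min_mean_count
  v <- v[keep, , drop = FALSE]
  c1 <- v[, i1, drop = FALSE]; c2 <- v[, i2, drop = FALSE]
  s1 <- rowSums(c1); s2 <- rowSums(c2)
  n1 <- length(i1); n2 <- length(i2)
  p_a <- vapply(seq_len(nrow(v)), function(i) {
    if (s1[i] + s2[i] == 0) return(1)
    stats::poisson.test(c(s2[i], s1[i]), c(n2, n1))$p.value
  }, numeric(1))
  l1 <- log2(c1 + 1); l2 <- log2(c2 + 1)
  lfc <- rowMeans(l2) - rowMeans(l1)
  p_b <- vapply(seq_len(nrow(v)), function(i) {
    if (stats::sd(l1[i, ]) == 0 && stats::sd(l2[i, ]) == 0) return(1)
    tryCatch(stats::t.test(l2[i, ], l1[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  padj_a <- stats::p.adjust(p_a, "BH")
  # method B tests within its fold-floor candidate set: the floor defines
  # which genes the method considers, BH is applied among those
  cand <- abs(lfc) >= log2(min_fold)
  padj_b <- rep(NA_real_, length(p_b))
  padj_b[cand] <- stats::p.adjust(p_b[cand], "BH")
  call_a <- padj_a < alpha
  call_b <- cand & !is.na(padj_b) & padj_b < alpha
  res <- data.frame(gene_id = rownames(v), log2_fc = lfc, p_a = p_a, p_b = p_b,
                    padj_a = padj_a, padj_b = padj_b, call_a = call_a,
                    call_b = call_b, robust = call_a & call_b,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Cross-species ortholog induction comparison
#'
#' Both matrices must be sample-mean scaled (every column mean 1, the
#' shared relative scale).  Per orthogroup the mean relative abundance
#' trajectory is computed for each species, the induction ratio is the
#' last time point over the first (with pseudocount `eps`), and the
#' species contrast is `log2(induction_A / induction_B)` -- positive
#' when the species-A member is induced more strongly.  Time courses
#' with different labels are aligned by nearest label.
#'
#' @param x_a,x_b `ExpressionMatrix`es for species A and B, sample-mean
#'   scaled.
#' @param ortholog_map `data.frame` with `orthogroup`, `gene_a`,
#'   `gene_b`.
#' @param gene_set Optional character vector of orthogroups (or species-A
#'   gene ids) to restrict to; must be non-empty after matching.
#' @param eps Pseudocount on the relative-abundance scale (default 0.01).
#' @return `data.frame` per orthogroup: induction ratios per species,
#'   `contrast` (log2 A over B) and a `missing` flag for orthogroups
#'   whose member is absent from a matrix (excluded from the contrast).
#' @export
induction_comparison <- function(x_a, x_b, ortholog_map, gene_set = NULL, eps = 0.01) {
  for (m in list(x_a, x_b)) {
    .assert(all(abs(colMeans(.values_of(m)) - 1) < 1e-6),
            "matrices must be sample-mean scaled (column means 1)")
  }
  map <- ortholog_map
  if (!is.null(gene_set)) {
    map <- map[map$orthogroup %in% gene_set | map$gene_a %in% gene_set, , drop = FALSE]
    .assert(nrow(map) > 0, "empty gene set after matching the ortholog map")
  }
  times_a <- sort(unique(x_a$meta$time))
  times_b <- sort(unique(x_b$meta$time))
  # align B's course onto A's labels by nearest label
  b_for_a <- times_b[vapply(times_a, function(t) which.min(abs(times_b - t)), integer(1))]
  mean_traj <- function(m, gene, times) {
    v <- .values_of(m)
    if (!gene %in% rownames(v)) return(NULL)
    vapply(times, function(t) mean(v[gene, m$meta$time == t]), numeric(1))
  }
  rows <- lapply(seq_len(nrow(map)), function(i) {
    ta <- mean_traj(x_a, map$gene_a[i], times_a)
    tb <- mean_traj(x_b, map$gene_b[i], b_for_a)
    if (is.null(ta) || is.null(tb)) {
      return(data.frame(orthogroup = map$orthogroup[i], induction_a = NA_real_,
                        induction_b = NA_real_, contrast = NA_real_, missing = TRUE))
    }
    ia <- (ta[length(ta)] + eps) / (ta[1] + eps)
    ib <- (tb[length(tb)] + eps) / (tb[1] + eps)
    data.frame(orthogroup = map$orthogroup[i], induction_a = ia, induction_b = ib,
               contrast = log2(ia / ib), missing = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
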