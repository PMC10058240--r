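# log10 upper-tail binomial probability P(X >= k), X ~ Bin(n, p);
# exact via pbinom on the log scale.  k <= 0 gives 0 (probability 1).
.log10_binom_tail <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Detect digital genomic footprints inside DHSs
#'
#' Wellington-style strand-aware statistic: for every candidate window W
#' inside a DHS, with flanking shoulders of `shoulder` bases, the
#' forward-strand evidence is the binomial upper-tail probability of
#' observing at least the observed number of forward cuts in the left
#' shoulder out of all forward cuts in (left shoulder + window), with
#' success probability `shoulder / (shoulder + width)`; the reverse
#' strand is scored symmetrically against the right shoulder.  The
#' footprint score is the sum of the two log10 p-values.  At each window
#' start the best-scoring width is kept, and maximal non-overlapping
#' candidates with score below `score_threshold` are selected greedily by
#' ascending score (ties to the leftmost start).
#'
#' @param profile A `CutProfile`.
#' @param dhs `GRanges` of DHS intervals to search within.
#' @param widths Candidate footprint widths (within 6-40 bp).
#' @param shoulder Shoulder width in bases (>= 5).
#' @param score_threshold Retain candidates scoring strictly below this
#'   (log10 p units, < 0).
#' @return `GRanges` of footprints with metadata `score`, `fp_width`,
#'   `time`; attribute `"skipped"` counts DHSs too narrow to search.
#' @export
detect_footprints <- function(profile, dhs, widths = seq(11L, 25L, 2L),
                              shoulder = 35L, score_threshold = -10) {
  .assert(all(widths >= 6 & widths <= 40), "widths must lie within [6, 40]")
  .assert(shoulder >= 5, "shoulder must be at least 5")
  .assert(score_threshold < 0, "score threshold must be negative (log10 p)")
  widths <- sort(as.integer(widths))
  res <- list(); skipped <- 0L
  for (ch in unique(as.character(GenomeInfoDb::seqnames(dhs)))) {
    if (!ch %in% names(profile$fwd)) next
    fwd <- profile$fwd[[ch]]; rev <- profile$rev[[ch]]
    cf <- cumsum(c(0, fwd)); cr <- cumsum(c(0, rev))
    sumF <- function(a, b) cf[b + 1L] - cf[a]
    sumR <- function(a, b) cr[b + 1L] - cr[a]
    d <- dhs[as.character(GenomeInfoDb::seqnames(dhs)) == ch]
    for (i in seq_along(d)) {
      s <- max(IRanges::start(d)[i], 1L); e <- min(IRanges::end(d)[i], length(fwd))
      if (e - s + 1L < min(widths) + 2L * shoulder) { skipped <- skipped + 1L; next }
      p_lo <- s + shoulder
      best_score <- NULL; best_width <- NULL
      for (w in widths) {
        p_hi <- e - w + 1L - shoulder
        if (p_hi < p_lo) next
        p_vec <- p_lo:p_hi
        kf <- sumF(p_vec - shoulder, p_vec - 1L)
        nf <- kf + sumF(p_vec, p_vec + w - 1L)
        kr <- sumR(p_vec + w, p_vec + w + shoulder - 1L)
        nr <- kr + sumR(p_vec, p_vec + w - 1L)
        pr <- shoulder / (shoulder + w)
        sc <- .log10_binom_tail(kf, nf, pr) + .log10_binom_tail(kr, nr, pr)
        if (is.null(best_score)) {
          best_score <- rep(Inf, p_hi - p_lo + 1L)
          best_width <- rep(NA_integer_, p_hi - p_lo + 1L)
        }
        idx <- seq_along(sc)
        upd <- sc < best_score[idx]
        best_score[idx][upd] <- sc[upd]
        best_width[idx][upd] <- w
      }
      if (is.null(best_score)) { skipped <- skipped + 1L; next }
      cand <- which(best_score < score_threshold)
      if (!length(cand)) next
      starts <- p_lo + cand - 1L
      scs <- best_score[cand]; ws <- best_width[cand]
      ord <- order(scs, starts)
      occupied <- rep(FALSE, e - s + 1L)
      keep <- logical(length(ord))
      for (j in ord) {
        a <- starts[j] - s + 1L; b <- a + ws[j] - 1L
        if (any(occupied[a:b])) next
        occupied[a:b] <- TRUE
        keep[j] <- TRUE
      }
      if (any(keep)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = starts[keep], end = starts[keep] + ws[keep] - 1L,
          score = scs[keep], fp_width = ws[keep])
      }
    }
  }
  if (!length(res)) {
    out <- GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                  score = numeric(0), fp_width = integer(0),
                                  time = numeric(0))
  } else {
    df <- do.call(rbind, res)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    out <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                  score = df$score, fp_width = df$fp_width,
                                  time = profile$time,
                                  seqlengths = profile$seqlengths)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Estimate hexamer cutting bias from a deproteinated control
#'
#' For every hexamer h: `rate(h) = (cuts with context h + pseudocount) /
#' (genomic occurrences of h + pseudocount)`, normalised to mean 1 over
#' the hexamers observed in the genome.  Cut context follows the
#' package-wide convention (3 bases either side of the nick, on the
#' strand of the cut); genomic occurrences count both strands.
#'
#' @param control A `CutProfile` with `treatment = "deproteinated"`.
#' @param genome Named `DNAStringSet` matching the profile's chromosomes.
#' @param pseudocount Added to both numerator and denominator.
#' @return Object of class `HexamerBiasTable`: list with `rate` (named
#'   4096-vector, mean 1), `pseudocount`, `total_cuts`, `absent`
#'   (hexamers never seen in the genome, whose rate is pinned at 1).
#' @export
estimate_hexamer_bias <- function(control, genome, pseudocount = 1) {
  .assert(control$treatment == "deproteinated",
          "bias must be estimated from a deproteinated control")
  .assert(sum(Biostrings::width(genome)) > 0, "zero-length genome")
  cuts <- numeric(4096); occ <- numeric(4096)
  for (ch in names(control$fwd)) {
    .assert(ch %in% names(genome), sprintf("chromosome %s absent from genome", ch))
    codes <- .base_codes(as.character(genome[[ch]]))
    L <- length(codes)
    if (L < 6L) next
    W <- .window_codes(codes, 6L)
    ok <- !is.na(W)
    occ <- occ + tabulate(W[ok] + 1L, 4096) + tabulate(.rc_codes(W[ok]) + 1L, 4096)
    fwd <- control$fwd[[ch]]; rev <- control$rev[[ch]]
    vf <- fwd[4:(L - 2L)]; cfd <- W
    sel <- ok & vf > 0
    if (any(sel)) {
      agg <- rowsum(vf[sel], cfd[sel])
      cuts[as.integer(rownames(agg)) + 1L] <- cuts[as.integer(rownames(agg)) + 1L] + agg[, 1]
    }
    vr <- rev[3:(L - 3L)]; crd <- .rc_codes(W)
    sel <- ok & vr > 0
    if (any(sel)) {
      agg <- rowsum(vr[sel], crd[sel])
      cuts[as.integer(rownames(agg)) + 1L] <- cuts[as.integer(rownames(agg)) + 1L] + agg[, 1]
    }
  }
  rate <- (cuts + pseudocount) / (occ + pseudocount)
  observed <- occ > 0
  rate[observed] <- rate[observed] / mean(rate[observed])
  rate[!observed] <- 1
  names(rate) <- .kmer_strings(6L)
  structure(list(rate = rate, pseudocount = pseudocount,
                 total_cuts = sum(cuts), absent = names(rate)[!observed]),
            class = "HexamerBiasTable")
}

#' @export
print.HexamerBiasTable <- function(x, ...) {
  cat(sprintf("HexamerBiasTable: %.0f control cuts, rate range [%.3f, %.3f], %d absent hexamer(s)\n",
              x$total_cuts, min(x$rate), max(x$rate), length(x$absent)))
  invisible(x)
}

.bias_rate_vector <- function(bias) {
  if (inherits(bias, "HexamerBiasTable")) bias$rate else bias
}

#' Expected relative cut proportions over a region under a bias table
#'
#' Each base gets the bias weight of its hexamer context (weight 1 where
#' the context is unavailable or contains N); weights are normalised to
#' sum to 1 over the region.
#'
#' @param bias A `HexamerBiasTable` or named 4096-vector of rates.
#' @param genome Named `DNAStringSet`.
#' @param region `GRanges` of length 1 (width >= 1).
#' @param strand `"both"` sums the two strand contexts per base; `"fwd"`
#'   or `"rev"` use a single strand.
#' @return Numeric vector of per-base proportions summing to 1.
#' @export
expected_cut_rates <- function(bias, genome, region, strand = c("both", "fwd", "rev")) {
  strand <- match.arg(strand)
  .assert(length(region) == 1, "one region at a time")
  ch <- as.character(GenomeInfoDb::seqnames(region))
  s <- IRanges::start(region); e <- IRanges::end(region)
  .assert(s >= 1 && e <= Biostrings::width(genome)[match(ch, names(genome))],
          "region outside chromosome bounds")
  bw <- .bias_weights(.bias_rate_vector(bias), as.character(genome[[ch]]))
  w <- switch(strand, both = bw$fwd[s:e] + bw$rev[s:e],
              fwd = bw$fwd[s:e], rev = bw$rev[s:e])
  w / sum(w)
}

# Two-component Gaussian mixture over x fitted by EM.  Deterministic
# initialisation: k-means started from the 20%/80% quantiles.  Returns
# parameters with the footprint component = lower mean.
.fit_flr_mixture <- function(x, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  q <- stats::quantile(x, c(0.2, 0.8), names = FALSE)
  if (diff(q) < 1e-8) {
    return(list(degenerate = TRUE, converged = FALSE, loglik = numeric(0),
                pi = c(0.5, 0.5), mu = c(q[1], q[1]), sd = c(1e-3, 1e-3)))
  }
  km <- stats::kmeans(x, centers = matrix(q, ncol = 1))
  mu <- as.vector(km$centers)
  sd <- vapply(1:2, function(k) {
    v <- stats::sd(x[km$cluster == k]); if (is.na(v) || v < 1e-3) 1e-3 else v
  }, numeric(1))
  pi <- pmax(tabulate(km$cluster, 2) / n, 1e-6)
  pi <- pi / sum(pi)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- cbind(log(pi[1]) + stats::dnorm(x, mu[1], sd[1], log = TRUE),
                log(pi[2]) + stats::dnorm(x, mu[2], sd[2], log = TRUE))
    m <- pmax(lg[, 1], lg[, 2])
    den <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(den)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    g <- exp(lg - den)   # responsibilities
    nk <- colSums(g)
    pi <- pmax(nk / n, 1e-9); pi <- pi / sum(pi)
    mu <- colSums(g * x) / nk
    sd <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / nk)
    sd <- pmax(sd, 1e-3)
  }
  ord <- order(mu)   # footprint component first (lower mean)
  list(degenerate = abs(diff(mu)) < 1e-6, converged = converged,
       loglik = ll_trace, pi = pi[ord], mu = mu[ord], sd = sd[ord])
}

#' Footprint likelihood ratio against hexamer cutting bias
#'
#' For every footprint a bias-corrected depletion statistic is computed:
#' `x = log((o_in / e_in) / (o_out / e_out))`, where `o` are observed
#' cuts (both strands, pseudocount 0.5) and `e` are bias-table expected
#' weights, inside the footprint and in its two shoulders.  A
#' two-component Gaussian mixture over x is fitted by EM (footprint
#' component = lower mean); the FLR of footprint i is the posterior
#' log-odds `log(pi_f f_f(x_i)) - log(pi_b f_b(x_i))`.  FLR >= 0 means
#' the depletion exceeds what sequence bias alone explains.
#'
#' @param footprints `GRanges` from [detect_footprints()] (>= 20 needed
#'   to fit the mixture).
#' @param profile The `CutProfile` the footprints were called on.
#' @param bias A `HexamerBiasTable` from a deproteinated control.
#' @param genome Named `DNAStringSet`.
#' @param shoulder Shoulder width used for `o_out`/`e_out` (default 35).
#' @return List with `footprints` (input plus metadata `x`, `flr`) and
#'   `fit` (class `MixtureFit`: weights, means, scales, log-likelihood
#'   trace, `converged`, `degenerate`).
#' @export
footprint_flr <- function(footprints, profile, bias, genome, shoulder = 35L) {
  n <- length(footprints)
  .assert(n >= 20, "at least 20 footprints are needed to fit the mixture")
  rate <- .bias_rate_vector(bias)
  x <- numeric(n)
  chs <- as.character(GenomeInfoDb::seqnames(footprints))
  for (ch in unique(chs)) {
    bw <- .bias_weights(rate, as.character(genome[[ch]]))
    wboth <- bw$fwd + bw$rev
    obs <- total_cuts(profile, ch)
    L <- length(obs)
    idx <- which(chs == ch)
    for (i in idx) {
      s <- IRanges::start(footprints)[i]; e <- IRanges::end(footprints)[i]
      ls <- max(1L, s - shoulder); re <- min(L, e + shoulder)
      o_in <- sum(obs[s:e]); e_in <- sum(wboth[s:e])
      out_idx <- c(if (ls <= s - 1L) ls:(s - 1L), if (e + 1L <= re) (e + 1L):re)
      o_out <- sum(obs[out_idx]); e_out <- sum(wboth[out_idx])
      x[i] <- log(((o_in + 0.5) / e_in) / ((o_out + 0.5) / e_out))
    }
  }
  fit <- .fit_flr_mixture(x)
  if (fit$degenerate) {
    warning("depletion statistics form a single component; all FLR set negative")
    flr <- rep(-1, n)
  } else {
    flr <- (log(fit$pi[1]) + stats::dnorm(x, fit$mu[1], fit$sd[1], log = TRUE)) -
      (log(fit$pi[2]) + stats::dnorm(x, fit$mu[2], fit$sd[2], log = TRUE))
  }
  if (!fit$converged && !fit$degenerate) {
    warning("EM did not converge within the iteration budget; best fit returned")
  }
  footprints$x <- x
  footprints$flr <- flr
  list(footprints = footprints, fit = structure(fit, class = "MixtureFit"))
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit: pi = (%.3f, %.3f), mu = (%.3f, %.3f), sd = (%.3f, %.3f), %s\n",
              x$pi[1], x$pi[2], x$mu[1], x$mu[2], x$sd[1], x$sd[2],
              if (isTRUE(x$degenerate)) "degenerate" else
                if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Filter footprints by FLR
#'
#' Retains footprints with `FLR >= 0` and reports the removed fraction
#' per time point.
#'
#' @param footprints `GRanges` with metadata `flr` and `time`.
#' @return List with `retained` (`GRanges`) and `report` (`data.frame`
#'   with `time`, `total`, `removed`, `reduction`).
#' @export
filter_footprints <- function(footprints) {
  if (!length(footprints)) {
    return(list(retained = footprints,
                report = data.frame(time = numeric(0), total = integer(0),
                                    removed = integer(0), reduction = numeric(0))))
  }
  .assert(!is.null(footprints$flr), "FLR must be assigned before filtering")
  keep <- footprints$flr >= 0
  tms <- if (is.null(footprints$time)) rep(NA_real_, length(footprints)) else footprints$time
  report <- do.call(rbind, lapply(split(seq_along(footprints), format(tms)), function(ii) {
    data.frame(time = tms[ii[1]], total = length(ii), removed = sum(!keep[ii]),
               reduction = sum(!keep[ii]) / length(ii))
  }))
  rownames(report) <- NULL
  list(retained = footprints[keep], report = report)
}

#' Extend footprints for motif scanning
#'
#' Pads each footprint by `pad` bases in both directions, clipped at
#' chromosome boundaries; records are not merged even if they overlap
#' after extension.
#'
#' @param footprints `GRanges` (seqlengths used for clipping when set).
#' @param pad Bases added on each side (>= 0).
#' @return `GRanges` of extended intervals (metadata preserved).
#' @export
extend_footprints <- function(footprints, pad = 4L) {
  .assert(pad >= 0, "pad must be non-negative")
  if (!length(footprints)) return(footprints)
  s <- pmax(IRanges::start(footprints) - pad, 1L)
  sl <- GenomeInfoDb::seqlengths(footprints)[as.character(GenomeInfoDb::seqnames(footprints))]
  e <- IRanges::end(footprints) + pad
  e <- ifelse(is.na(sl), e, pmin(e, sl))
  IRanges::ranges(footprints) <- IRanges::IRanges(s, e)
  footprints
}

#' Write footprints as BED with score and FLR columns
#' @param footprints `GRanges` with `score` and optionally `flr`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_footprints_bed <- function(footprints, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(footprints)),
                   start = IRanges::start(footprints) - 1L,
                   end = IRanges::end(footprints),
                   name = sprintf("fp_%d", seq_along(footprints)),
                   score = footprints$score,
                   flr = if (is.null(footprints$flr)) NA_real_ else footprints$flr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
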