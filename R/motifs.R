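#' Build a position weight matrix from base counts
#'
#' Standard PWM construction: per-column probabilities from counts with a
#' pseudocount, and a log-likelihood-ratio score matrix against a
#' background base composition (log2, i.e. bits).
#'
#' @param counts 4 x width numeric matrix of base counts, rows in order
#'   A, C, G, T.
#' @param pseudocount Added to every cell before normalising.
#' @param background Named numeric of background base frequencies
#'   (A, C, G, T), summing to 1.
#' @param id Motif identifier.
#' @param group Optional motif-group label.
#' @return An object of class `PWM` with fields `id`, `width`, `probs`,
#'   `background`, `scores` (log2 likelihood ratios) and `group`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            id = "motif", group = NULL) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == 4, "counts must have 4 rows (A, C, G, T)")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(all(colSums(counts) > 0 | pseudocount > 0),
          "all-zero column with zero pseudocount")
  .assert(abs(sum(background) - 1) < 1e-9 && all(background > 0),
          "background must be positive frequencies summing to 1")
  w <- ncol(counts)
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
  bg <- background[c("A", "C", "G", "T")]
  scores <- log2(probs / bg)
  structure(list(id = id, width = w, probs = probs, background = bg,
                 scores = scores, group = group), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d%s), consensus %s\n", x$id, x$width,
              if (is.null(x$group)) "" else paste0(", group ", x$group),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param pwm A `PWM`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Base composition of a set of sequences
#' @param seqs Character vector or `DNAStringSet`.
#' @return Named frequencies over A, C, G, T (ambiguous bases ignored).
#' @export
sequence_background <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    f <- colSums(Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"), drop = FALSE])
  } else {
    codes <- unlist(lapply(as.character(seqs), .base_codes))
    codes <- codes[!is.na(codes)]
    f <- tabulate(codes + 1L, nbins = 4L)
    names(f) <- c("A", "C", "G", "T")
  }
  f / sum(f)
}

# Exact (or, for wide motifs, finely binned) null distribution of PWM
# scores on background-random sequences.  In exact mode the partial sums
# are accumulated column-by-column exactly as a per-sequence left-to-right
# summation would, so score values are bitwise identical to scanned scores
# and tail probabilities agree with exhaustive enumeration.
# Falls back to integer binning (bin width in bits) when the number of
# distinct exact score values would exceed `max_exact`.
.pwm_score_tail <- function(pwm, bin = 1e-3, max_exact = 70000L) {
  sc <- pwm$scores
  bg <- pwm$background
  w <- pwm$width
  vals <- 0; prb <- 1
  exact <- TRUE
  for (j in seq_len(w)) {
    nv <- rep(vals, each = 4L) + rep(sc[, j], times = length(vals))
    np <- rep(prb, each = 4L) * rep(bg, times = length(vals))
    key <- sprintf("%.17g", nv)
    first <- !duplicated(key)
    agg <- rowsum(np, key, reorder = FALSE)
    vals <- nv[first]
    prb <- as.vector(agg)[match(key[first], rownames(agg))]
    if (length(vals) > max_exact) { exact <- FALSE; break }
  }
  if (exact) {
    o <- order(vals)
    vals <- vals[o]; prb <- prb[o]
    tail <- rev(cumsum(rev(prb)))
    return(list(mode = "exact", values = vals, tail = tail))
  }
  # binned dynamic programme over integer score units
  isc <- matrix(as.integer(round(sc / bin)), nrow = 4)
  cur <- 1; cur_lo <- 0L
  for (j in seq_len(w)) {
    cj <- isc[, j]
    new_lo <- cur_lo + min(cj)
    new_hi <- cur_lo + length(cur) - 1L + max(cj)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + cj[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * bg[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  vals <- seq.int(cur_lo, cur_lo + length(cur) - 1L)
  keep <- cur > 0
  vals <- vals[keep]; cur <- cur[keep]
  tail <- rev(cumsum(rev(cur)))
  list(mode = "binned", values = vals, tail = tail, bin = bin, int_scores = isc)
}

# P(S >= s - tol): the tolerance groups score values that are
# mathematically tied but differ in the last float bits because different
# summation paths round differently.
.tail_lookup_exact <- function(tl, s, tol = 1e-9) {
  out <- rep(NA_real_, length(s))
  valid <- which(!is.na(s))
  if (!length(valid)) return(out)
  i <- findInterval(s[valid] - tol, tl$values) + 1L   # first value >= s - tol
  n <- length(tl$values)
  v <- numeric(length(valid))
  ok <- i <= n
  v[ok] <- tl$tail[i[ok]]
  out[valid] <- v
  out
}

.ensure_tail <- function(pwm) {
  if (is.null(attr(pwm, "score_tail"))) {
    attr(pwm, "score_tail") <- .pwm_score_tail(pwm)
  }
  pwm
}

# Score every window start of a code vector; NA where the window is
# incomplete or contains an ambiguous base.
.scan_codes <- function(scores, codes, w) {
  n <- length(codes)
  if (n < w) return(numeric(0))
  s <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    colj <- scores[, j]
    s <- s + colj[codes[j:(n - w + j)] + 1L]
  }
  s
}

#' Scan a sequence with a PWM, reporting exact p-values
#'
#' Every window (and, when `both_strands`, every reverse-complement
#' window) is scored with the PWM's log-likelihood-ratio matrix; a hit's
#' p-value is the probability that a background-random sequence of the
#' motif's width scores at least as high, computed from the exact null
#' score distribution (dynamic programme over columns; for wide motifs a
#' binned distribution with 0.001-bit resolution is used).  Windows
#' containing `N` are skipped.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param sequence Character scalar or `DNAString` over A, C, G, T, N.
#' @param p_threshold Report hits with p-value at or below this.
#' @param both_strands Also scan the reverse complement.
#' @return `data.frame` with columns `motif_id`, `start`, `end`, `strand`,
#'   `score`, `p` (1-based closed coordinates on the input sequence).
#' @export
scan_sequence <- function(pwm, sequence, p_threshold = 1e-4, both_strands = TRUE) {
  seq_chr <- as.character(sequence)
  n <- nchar(seq_chr)
  w <- pwm$width
  empty <- data.frame(motif_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0), p = numeric(0))
  if (n < w) return(empty)
  pwm <- .ensure_tail(pwm)
  tl <- attr(pwm, "score_tail")
  codes <- .base_codes(seq_chr)

  score_strand <- function(cod) {
    if (identical(tl$mode, "binned")) {
      si <- .scan_codes(tl$int_scores, cod, w)   # integer-unit scores for p lookup
      sx <- .scan_codes(pwm$scores, cod, w)
      list(p = ifelse(is.na(si), NA, .tail_lookup_exact(tl, si)), score = sx)
    } else {
      sx <- .scan_codes(pwm$scores, cod, w)
      list(p = ifelse(is.na(sx), NA, .tail_lookup_exact(tl, sx)), score = sx)
    }
  }

  fw <- score_strand(codes)
  keep <- !is.na(fw$p) & fw$p <= p_threshold
  hits <- data.frame(motif_id = rep(pwm$id, sum(keep)), start = which(keep),
                     end = which(keep) + w - 1L, strand = rep("+", sum(keep)),
                     score = fw$score[keep], p = fw$p[keep])
  if (both_strands) {
    rc <- rev(3L - codes)
    rv <- score_strand(rc)
    keepr <- !is.na(rv$p) & rv$p <= p_threshold
    j <- which(keepr)
    if (length(j)) {
      hits <- rbind(hits, data.frame(motif_id = pwm$id, start = n - j - w + 2L,
                                     end = n - j + 1L, strand = "-",
                                     score = rv$score[keepr], p = rv$p[keepr]))
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan genomic regions with a motif library
#'
#' Convenience wrapper applying [scan_sequence()] to every region of a
#' genome and translating hit coordinates back to the chromosome.
#'
#' @param pwms List of `PWM` objects.
#' @param genome Named `DNAStringSet`.
#' @param regions `GRanges` of regions to scan (`NULL` scans whole
#'   chromosomes).
#' @param p_threshold,both_strands Passed to [scan_sequence()].
#' @return Hit `data.frame` with `chrom` plus the [scan_sequence()]
#'   columns; duplicate hits from overlapping regions are removed.
#' @export
scan_genome <- function(pwms, genome, regions = NULL, p_threshold = 1e-4,
                        both_strands = TRUE) {
  if (is.null(regions)) {
    regions <- GenomicRanges::GRanges(names(genome),
                                      IRanges::IRanges(1L, Biostrings::width(genome)))
  }
  pwms <- lapply(pwms, .ensure_tail)
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    chrom <- as.character(GenomeInfoDb::seqnames(regions))[i]
    rs <- IRanges::start(regions)[i]; re <- IRanges::end(regions)[i]
    seq_i <- as.character(Biostrings::subseq(genome[[chrom]], rs, re))
    hh <- lapply(pwms, scan_sequence, sequence = seq_i,
                 p_threshold = p_threshold, both_strands = both_strands)
    hh <- do.call(rbind, hh)
    if (nrow(hh)) {
      hh$start <- hh$start + rs - 1L
      hh$end <- hh$end + rs - 1L
      hh <- cbind(chrom = chrom, hh)
    } else {
      hh <- cbind(chrom = character(0), hh)
    }
    out[[i]] <- hh
  }
  hits <- do.call(rbind, out)
  hits <- unique(hits)
  rownames(hits) <- NULL
  hits
}

#' Attach motif-group labels to hits
#'
#' @param hits Hit `data.frame` with a `motif_id` column.
#' @param group_map `data.frame` with columns `motif_id`, `group`.
#' @return `hits` with a `group` column; motifs absent from the map are
#'   labelled `"ungrouped"` (with a warning giving their count).
#' @export
assign_groups <- function(hits, group_map) {
  g <- group_map$group[match(hits$motif_id, group_map$motif_id)]
  n_un <- sum(is.na(g))
  if (n_un > 0) {
    warning(sprintf("%d hit(s) from motifs absent from the group map; labelled 'ungrouped'",
                    n_un))
    g[is.na(g)] <- "ungrouped"
  }
  hits$group <- g
  hits
}

#' Count non-overlapping motif occurrences
#'
#' Greedy selection by ascending p-value (ties broken by leftmost start,
#' then motif id): a hit is kept if it overlaps no previously kept hit of
#' the same scope unit.  Counts are reported per scope unit.
#'
#' @param hits Hit `data.frame` (needs `start`, `end`, `p`, `motif_id`,
#'   and `group` when `scope = "per-group"`).
#' @param region Optional `c(start, end)`; only hits wholly inside are
#'   considered.
#' @param scope Count per motif id or per motif group.
#' @return Named integer vector of counts.
#' @export
count_nonoverlapping <- function(hits, region = NULL,
                                 scope = c("per-group", "per-motif")) {
  scope <- match.arg(scope)
  key <- if (scope == "per-group") "group" else "motif_id"
  .assert(key %in% names(hits), sprintf("hits need a '%s' column for this scope", key))
  if (!is.null(region)) {
    hits <- hits[hits$start >= region[1] & hits$end <= region[2], , drop = FALSE]
  }
  if (!nrow(hits)) return(setNames(integer(0), character(0)))
  ord <- order(hits$p, hits$start, hits$motif_id)
  hits <- hits[ord, , drop = FALSE]
  counts <- integer(0)
  kept <- list()
  for (i in seq_len(nrow(hits))) {
    u <- hits[[key]][i]
    ivs <- kept[[u]]
    s <- hits$start[i]; e <- hits$end[i]
    if (!is.null(ivs) && any(s <= ivs[, 2] & e >= ivs[, 1])) next
    kept[[u]] <- rbind(ivs, c(s, e))
    counts[u] <- (if (is.na(counts[u])) 0L else counts[u]) + 1L
  }
  counts[is.na(counts)] <- 0L
  counts
}

#' Count light-responsive elements over a gene window
#'
#' Counts non-overlapping motif-family occurrences in the window running
#' from 1.5 kb upstream of the TSS to the end of the coding sequence, in
#' gene orientation (reflected for minus-strand genes) and clipped at
#' chromosome boundaries.
#'
#' @param gene One row of a gene table (needs `strand`, `tss`,
#'   `cds_start`, `cds_end`, `chrom`).
#' @param hits Hit `data.frame` for the gene's chromosome.
#' @param family_map `data.frame` mapping `motif_id` to `group`
#'   (families).
#' @param upstream Window extent upstream of the TSS (default 1500).
#' @param seqlength Chromosome length for clipping (optional).
#' @return Named integer vector: non-overlapping count per family (all
#'   families of the map reported, zeros included).
#' @export
count_lres <- function(gene, hits, family_map, upstream = 1500L, seqlength = NULL) {
  if (gene$strand == "+") {
    ws <- gene$tss - upstream; we <- gene$cds_end
  } else {
    ws <- gene$cds_start; we <- gene$tss + upstream
  }
  if (ws < 1) { ws <- 1L }
  if (!is.null(seqlength) && we > seqlength) we <- seqlength
  if ("chrom" %in% names(hits) && !is.null(gene$chrom)) {
    hits <- hits[hits$chrom == gene$chrom, , drop = FALSE]
  }
  hits <- assign_groups(hits[hits$motif_id %in% family_map$motif_id, , drop = FALSE],
                        family_map)
  counts <- count_nonoverlapping(hits, region = c(ws, we), scope = "per-group")
  fams <- unique(family_map$group)
  out <- setNames(integer(length(fams)), fams)
  out[names(counts)] <- counts
  out
}

# Best-offset Pearson correlation between two PWMs' probability columns,
# considering the reverse complement, with at least `min_overlap` aligned
# columns.
.pwm_similarity <- function(a, b, min_overlap = 4L) {
  pa <- a$probs
  best <- -1
  for (pb in list(b$probs, b$probs[4:1, ncol(b$probs):1, drop = FALSE])) {
    wa <- ncol(pa); wb <- ncol(pb)
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(1, 1 + off):min(wa, wb + off)
      ib <- ia - off
      if (length(ia) < min_overlap) next
      r <- suppressWarnings(stats::cor(as.vector(pa[, ia]), as.vector(pb[, ib])))
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

#' Cluster PWMs into semi-redundant motif groups
#'
#' Stand-in similarity clustering: single-linkage on the best-offset
#' Pearson correlation of probability columns (reverse complement
#' considered), cut at `similarity_threshold`.
#'
#' @param pwms List of `PWM` objects (at least 2).
#' @param similarity_threshold Correlation above which motifs are linked.
#' @return `data.frame` with columns `motif_id`, `group` (labels
#'   `"cluster_1"`, ... in order of first member).
#' @export
cluster_pwms <- function(pwms, similarity_threshold = 0.8) {
  .assert(length(pwms) >= 2, "need at least two motifs to cluster")
  n <- length(pwms)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - .pwm_similarity(pwms[[i]], pwms[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = 1 - similarity_threshold)
  relabel <- match(cl, unique(cl))
  data.frame(motif_id = vapply(pwms, `[[`, character(1), "id"),
             group = paste0("cluster_", relabel), stringsAsFactors = FALSE)
}

#' Write a motif library in MEME format
#' @param pwms List of `PWM` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies", sprintf("A %.5f C %.5f G %.5f T %.5f",
                                                        bg["A"], bg["C"], bg["G"], bg["T"]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width), con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$probs["A", j], p$probs["C", j],
                         p$probs["G", j], p$probs["T", j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif library in MEME format
#' @param path MEME-format motif file.
#' @param pseudocount Pseudocount applied when rebuilding score matrices.
#' @return List of `PWM` objects.
#' @export
read_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF ", lines)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + grep("letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]),
                  numeric(4)))
    probs <- t(m)  # 4 x w
    pwms[[id]] <- pwm_from_counts(probs * 1000, pseudocount = pseudocount,
                                  background = bg, id = id)
  }
  pwms
}

#' Read or write a motif-to-group map as TSV
#' @param path TSV file with columns `motif_id`, `group`.
#' @return `data.frame` with those columns.
#' @export
read_group_map <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_group_map
#' @param group_map `data.frame` with columns `motif_id`, `group`.
#' @export
write_group_map <- function(group_map, path) {
  utils::write.table(group_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
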