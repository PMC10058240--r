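#' Background motif-group frequencies
#'
#' The expected per-group proportions against which gene-set or footprint
#' cistromes are compared.  The caller supplies hits already restricted
#' to the background region set (typically hyperconserved DHSs
#' intersected with expressed gene loci; see [restrict_hits()] and
#' [gene_locus_windows()]).
#'
#' @param hits Hit `data.frame` with a `motif_id` column (a `group`
#'   column is added from `group_map` when absent).
#' @param group_map `data.frame` mapping `motif_id` to `group`.
#' @return Named numeric of per-group proportions (summing to 1).
#' @export
background_frequencies <- function(hits, group_map) {
  .assert(nrow(hits) > 0, "empty background hit set")
  if (!"group" %in% names(hits)) hits <- assign_groups(hits, group_map)
  tab <- table(hits$group)
  p <- as.numeric(tab) / sum(tab)
  setNames(p, names(tab))
}

#' Motif-group enrichment log-ratio against a background
#'
#' Per group, `log2((obs_prop + eps) / (exp_prop + eps))` where `eps =
#' pseudocount / total observed hits`; positive values mean the group is
#' found more frequently than expected from the background.
#'
#' @param hits Observed hit `data.frame` for the query set (gene set or
#'   footprint set), with `group` labels.
#' @param background Named expected proportions from
#'   [background_frequencies()]; every observed group must be present.
#' @param pseudocount Hits-scale pseudocount (default 1).
#' @return Object of class `EnrichmentResult`: `data.frame` with
#'   `group`, `observed`, `obs_prop`, `exp_prop`, `log_ratio`.
#' @export
enrichment_log_ratio <- function(hits, background, pseudocount = 1) {
  .assert(nrow(hits) > 0, "empty observed hit set")
  .assert("group" %in% names(hits), "hits must carry group labels")
  .assert(all(unique(hits$group) %in% names(background)),
          "observed group absent from the background universe")
  obs <- table(factor(hits$group, levels = names(background)))
  total <- sum(obs)
  eps <- pseudocount / total
  obs_prop <- as.numeric(obs) / total
  exp_prop <- as.numeric(background)
  res <- data.frame(group = names(background), observed = as.integer(obs),
                    obs_prop = obs_prop, exp_prop = exp_prop,
                    log_ratio = log2((obs_prop + eps) / (exp_prop + eps)),
                    stringsAsFactors = FALSE)
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Restrict motif hits to a region set
#'
#' Keeps hits whose interval overlaps the (merged) regions by at least
#' one base.
#'
#' @param hits Hit `data.frame` with `chrom`, `start`, `end`.
#' @param regions `GRanges`.
#' @return The overlapping subset of `hits`.
#' @export
restrict_hits <- function(hits, regions) {
  if (!nrow(hits)) return(hits)
  hg <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start, hits$end))
  hits[IRanges::overlapsAny(hg, GenomicRanges::reduce(regions), ignore.strand = TRUE), ,
       drop = FALSE]
}

#' Depth-compensated motif-group proportions per time point
#'
#' Within each time point, per-group hit counts are divided by the total
#' grouped hits of that time point, so different sequencing depths and
#' footprint totals cancel.
#'
#' @param hits_by_time Named list (one element per time point) of hit
#'   `data.frame`s with `group` labels.
#' @return Matrix, groups x time points, each column summing to 1; time
#'   points with zero hits are dropped with a warning.
#' @export
dgf_motif_proportions <- function(hits_by_time) {
  nz <- vapply(hits_by_time, NROW, integer(1)) > 0
  if (any(!nz)) {
    warning(sprintf("time point(s) %s have no hits and are excluded",
                    paste(names(hits_by_time)[!nz], collapse = ", ")))
  }
  hits_by_time <- hits_by_time[nz]
  .assert(length(hits_by_time) > 0, "no time point with hits")
  groups <- sort(unique(unlist(lapply(hits_by_time, function(h) unique(h$group)))))
  out <- vapply(hits_by_time, function(h) {
    tab <- table(factor(h$group, levels = groups))
    as.numeric(tab) / sum(tab)
  }, numeric(length(groups)))
  out <- matrix(out, nrow = length(groups),
                dimnames = list(groups, names(hits_by_time)))
  out
}

#' Mean-centre motif trajectories across the time course
#'
#' Subtracts each group's across-time mean, so positive values mark time
#' points with greater-than-average abundance of that group.
#'
#' @param proportions Matrix, groups x time points (e.g. from
#'   [dgf_motif_proportions()]).
#' @return Object of class `TrajectoryMatrix`: the centred matrix with
#'   attribute `centered = TRUE`.
#' @export
mean_center_trajectories <- function(proportions) {
  out <- proportions - rowMeans(proportions)
  attr(out, "centered") <- TRUE
  class(out) <- c("TrajectoryMatrix", class(out))
  out
}

#' Correlation of each light time point with the dark sample
#'
#' Pearson (or Spearman) correlation, across motif groups, between the
#' dark column of a centred trajectory matrix and each light column.
#' Negative values mean groups abundant in the dark become depleted at
#' that light time point, and vice versa.
#'
#' @param centered `TrajectoryMatrix` (>= 3 groups), dark = first column
#'   by time order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named numeric of correlations, one per light time point;
#'   zero-variance columns yield `NA` with a warning.
#' @export
dark_light_correlation <- function(centered, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .assert(isTRUE(attr(centered, "centered")), "trajectories must be mean-centred")
  .assert(nrow(centered) >= 3, "need at least 3 motif groups")
  times <- suppressWarnings(as.numeric(colnames(centered)))
  ord <- if (anyNA(times)) seq_len(ncol(centered)) else order(times)
  m <- centered[, ord, drop = FALSE]
  dark <- m[, 1]
  out <- vapply(2:ncol(m), function(j) {
    if (stats::sd(dark) == 0 || stats::sd(m[, j]) == 0) return(NA_real_)
    stats::cor(dark, m[, j], method = method)
  }, numeric(1))
  names(out) <- colnames(m)[-1]
  if (anyNA(out)) warning("zero-variance column; correlation undefined (NA)")
  out
}
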