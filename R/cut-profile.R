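#' Per-base DNase I cut profile
#'
#' A `CutProfile` stores strand-specific 5' cut counts for one sample of a
#' DNase-seq experiment: for every chromosome, one integer vector per strand
#' whose i-th element is the number of cut events assigned to base i.  A cut
#' is assigned to the base immediately 3' of the nick on the strand of the
#' read, so forward- and reverse-strand vectors of the same chromosome have
#' the same length but independent counts.
#'
#' @param fwd,rev Named lists of non-negative integer vectors, one element
#'   per chromosome, identical names and lengths across the two strands.
#' @param time Time-point label in hours (numeric; `NA` for a control).
#' @param replicate Replicate index.
#' @param species Species label.
#' @param treatment `"nuclei"` for a chromatin sample, `"deproteinated"` for
#'   the naked-DNA cutting-bias control.
#' @param label Optional free-text sample label.
#'
#' @return An object of class `CutProfile` with fields `fwd`, `rev`,
#'   `seqlengths`, `library_size` and the sample metadata.
#' @export
cut_profile <- function(fwd, rev, time = NA_real_, replicate = 1L,
                        species = "A", treatment = c("nuclei", "deproteinated"),
                        label = NULL) {
  treatment <- match.arg(treatment)
  .assert(is.list(fwd) && is.list(rev), "fwd and rev must be lists of per-chromosome vectors")
  .assert(identical(names(fwd), names(rev)), "fwd and rev must cover the same chromosomes")
  .assert(!is.null(names(fwd)), "chromosome vectors must be named")
  for (chr in names(fwd)) {
    .assert(length(fwd[[chr]]) == length(rev[[chr]]),
            sprintf("strand vectors of %s differ in length", chr))
    .assert(all(fwd[[chr]] >= 0) && all(rev[[chr]] >= 0), "cut counts must be non-negative")
  }
  fwd <- lapply(fwd, function(v) as.integer(round(v)))
  rev <- lapply(rev, function(v) as.integer(round(v)))
  structure(list(
    fwd = fwd, rev = rev,
    seqlengths = vapply(fwd, length, integer(1)),
    library_size = sum(vapply(fwd, sum, numeric(1))) + sum(vapply(rev, sum, numeric(1))),
    time = time, replicate = replicate, species = species,
    treatment = treatment,
    label = label %||% sprintf("%s_t%s_r%d_%s", species, format(time), replicate, treatment)
  ), class = "CutProfile")
}

#' @export
print.CutProfile <- function(x, ...) {
  cat(sprintf("CutProfile '%s': %d chromosome(s), %.0f cuts, treatment=%s, t=%s h\n",
              x$label, length(x$fwd), x$library_size, x$treatment, format(x$time)))
  invisible(x)
}

#' Total (both-strand) cut counts of one chromosome
#' @param profile A `CutProfile`.
#' @param chrom Chromosome name.
#' @return Integer vector of per-base counts, forward plus reverse strand.
#' @export
total_cuts <- function(profile, chrom) {
  .assert(chrom %in% names(profile$fwd), sprintf("unknown chromosome '%s'", chrom))
  profile$fwd[[chrom]] + profile$rev[[chrom]]
}

#' Depth-normalise a cut profile to cuts per million
#'
#' Scales every per-base count by `1e6 / library_size` so profiles of
#' different sequencing depth are comparable, mirroring the per-sample read
#' normalisation used for accessibility profiles.
#'
#' @param profile A `CutProfile`.
#' @return A list with numeric lists `fwd`, `rev` and `total` (per
#'   chromosome), plus the scale factor used.
#' @export
cut_cpm <- function(profile) {
  .assert(profile$library_size > 0, "cannot normalise a profile with zero cuts")
  k <- 1e6 / profile$library_size
  fwd <- lapply(profile$fwd, function(v) v * k)
  rev <- lapply(profile$rev, function(v) v * k)
  total <- mapply(function(a, b) a + b, fwd, rev, SIMPLIFY = FALSE)
  list(fwd = fwd, rev = rev, total = total, scale = k)
}

# Dense per-base vector -> GRanges of constant-value runs (bedGraph model).
.vector_to_bedgraph_gr <- function(v, chrom) {
  r <- rle(as.numeric(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts[keep], ends[keep]),
                         score = r$values[keep])
}

#' Write a cut profile as a pair of bedGraph files
#'
#' One file per strand (`<prefix>.fwd.bedGraph`, `<prefix>.rev.bedGraph`),
#' zero runs omitted.
#'
#' @param profile A `CutProfile`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_cut_profile <- function(profile, prefix) {
  paths <- c(fwd = paste0(prefix, ".fwd.bedGraph"), rev = paste0(prefix, ".rev.bedGraph"))
  for (strand in c("fwd", "rev")) {
    grs <- lapply(names(profile[[strand]]), function(chr)
      .vector_to_bedgraph_gr(profile[[strand]][[chr]], chr))
    gr <- do.call(c, grs)
    rtracklayer::export(gr, paths[[strand]], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a cut profile from strand-specific bedGraph files
#'
#' @param fwd_path,rev_path bedGraph files with forward-/reverse-strand cuts.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @inheritParams cut_profile
#' @return A `CutProfile`.
#' @export
read_cut_profile <- function(fwd_path, rev_path, seqlengths, time = NA_real_,
                             replicate = 1L, species = "A",
                             treatment = c("nuclei", "deproteinated"), label = NULL) {
  treatment <- match.arg(treatment)
  read_one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    out <- lapply(names(seqlengths), function(chr) {
      v <- numeric(seqlengths[[chr]])
      g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chr]
      if (length(g)) {
        w <- IRanges::width(g)
        pos <- sequence(w) - 1L + rep(IRanges::start(g), w)
        v[pos] <- rep(g$score, w)
      }
      v
    })
    names(out) <- names(seqlengths)
    out
  }
  cut_profile(read_one(fwd_path), read_one(rev_path), time = time,
              replicate = replicate, species = species, treatment = treatment,
              label = label)
}
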