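# Per-base relative cutting weights implied by a hexamer bias table.
#
# Convention (fixed package-wide): a cut is assigned to the base
# immediately 3' of the nick on the strand of the read; its hexamer
# context is the 3 bases either side of the nick.  For a forward-strand
# cut at base i this is plus-strand bases (i-3)..(i+2); for a
# reverse-strand cut at base i it is the reverse complement of
# plus-strand bases (i-2)..(i+3).  Positions whose context leaves the
# chromosome or contains N get weight 1.
.bias_weights <- function(bias_table, seq_chr) {
  rate <- unname(bias_table[.kmer_strings(6L)])
  .assert(!anyNA(rate), "bias table must name all 4096 hexamers")
  codes <- .base_codes(seq_chr)
  L <- length(codes)
  W <- .window_codes(codes, 6L)
  bf <- rate[W + 1L]; bf[is.na(bf)] <- 1
  br <- rate[.rc_codes(W) + 1L]; br[is.na(br)] <- 1
  fwd <- rep(1, L); rev <- rep(1, L)
  if (L >= 6L) {
    fwd[4:(L - 2L)] <- bf
    rev[3:(L - 3L)] <- br
  }
  list(fwd = fwd, rev = rev)
}

#' Simulate DNase cut profiles for a time course plus a bias-only control
#'
#' Draws per-base, per-strand cut counts from a Poisson model whose rate
#' at each base is the product of sequencing depth, local accessibility at
#' that time point, the hexamer cutting bias of the cut's sequence
#' context, and -- inside a footprint occupied at that time point -- the
#' protection factor `phi`.  Accessibility is `background_fraction`
#' genome-wide, rises to 1 across planted DHSs (50-bp linear shoulders),
#' and is multiplied by `upstream_gain` over the 500 bp upstream of every
#' TSS at the intermediate light time points (0.5-4 h), emulating
#' light-induced promoter opening.  The deproteinated control has uniform
#' accessibility, no footprints, and the same hexamer bias.
#'
#' @param scenario A [synthetic_scenario()].
#' @param genome Named `DNAStringSet` (after motif planting).
#' @param truth Truth list carrying `dhs`, `genes`, `footprints` and
#'   `occupancy` (may be empty for a featureless simulation).
#' @return List with `profiles` (named list of `CutProfile`, one per time
#'   point, names `as.character(time_points)`) and `control` (deproteinated
#'   `CutProfile`).
#' @export
simulate_cut_profiles <- function(scenario, genome, truth) {
  seq_chr <- as.character(genome[[1]])
  chrom <- names(genome)[1]
  L <- nchar(seq_chr)
  tp <- scenario$time_points
  bw <- .bias_weights(scenario$bias_profile, seq_chr)
  phi <- scenario$footprint_protection

  acc <- rep(scenario$background_fraction, L)
  dhs <- truth$dhs
  if (!is.null(dhs) && length(dhs)) {
    bg <- scenario$background_fraction
    for (i in seq_along(dhs)) {
      s <- IRanges::start(dhs)[i]; e <- IRanges::end(dhs)[i]
      acc[s:e] <- 1
      if (s > 1L) {
        lj <- max(1L, s - 50L):(s - 1L)
        acc[lj] <- pmax(acc[lj], bg + (1 - bg) * (seq_along(lj) / 51))
      }
      if (e < L) {
        rj <- (e + 1L):min(L, e + 50L)
        acc[rj] <- pmax(acc[rj], bg + (1 - bg) * (rev(seq_along(rj)) / 51))
      }
    }
  }

  genes <- truth$genes
  gain_mult <- rep(1, L)
  if (!is.null(genes) && nrow(genes)) {
    loss <- scenario$downstream_loss %||% 1
    for (i in seq_len(nrow(genes))) {
      if (genes$strand[i] == "+") {
        up <- max(1L, genes$tss[i] - 500L):max(1L, genes$tss[i] - 1L)
        dn <- genes$tss[i]:min(L, genes$tss[i] + 499L)
      } else {
        up <- min(L, genes$tss[i] + 1L):min(L, genes$tss[i] + 500L)
        dn <- max(1L, genes$tss[i] - 499L):genes$tss[i]
      }
      gain_mult[up] <- gain_mult[up] * scenario$upstream_gain
      gain_mult[dn] <- gain_mult[dn] * loss
    }
  }

  fp <- truth$footprints
  occ <- truth$occupancy
  profiles <- vector("list", length(tp))
  names(profiles) <- as.character(tp)
  half_depth <- scenario$peak_depth / 2
  for (k in seq_along(tp)) {
    t <- tp[k]
    acc_t <- acc
    if (t > min(tp) && t < max(tp)) acc_t <- acc_t * gain_mult
    fac <- rep(1, L)
    if (!is.null(fp) && length(fp)) {
      occupied <- which(occ[, k])
      for (i in occupied) {
        fac[IRanges::start(fp)[i]:IRanges::end(fp)[i]] <- phi
      }
    }
    base_rate <- half_depth * acc_t * fac
    set.seed(component_seed(scenario$seed, paste0("cuts_", as.character(t))))
    fwd <- stats::rpois(L, base_rate * bw$fwd)
    rev <- stats::rpois(L, base_rate * bw$rev)
    profiles[[k]] <- cut_profile(setNames(list(fwd), chrom), setNames(list(rev), chrom),
                                 time = t, treatment = "nuclei",
                                 label = sprintf("nuclei_t%s", as.character(t)))
  }

  set.seed(component_seed(scenario$seed, "cuts_control"))
  cd <- scenario$control_depth / 2
  ctrl_fwd <- stats::rpois(L, cd * bw$fwd)
  ctrl_rev <- stats::rpois(L, cd * bw$rev)
  control <- cut_profile(setNames(list(ctrl_fwd), chrom), setNames(list(ctrl_rev), chrom),
                         time = NA_real_, treatment = "deproteinated",
                         label = "deproteinated_control")
  list(profiles = profiles, control = control)
}
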